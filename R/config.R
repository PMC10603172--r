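#' Simulation configuration
#'
#' Bundles every run parameter of the coupled-dyad simulator. The defaults
#' are the reference conditions under which all shipped analyses operate:
#' 500 recorded turns, decay \code{alpha = 0.1}, receptivity
#' \code{influence = 1}, per-agent uniform noise on (-0.5, 0.5), and initial
#' states drawn from the same interval for both agents.
#'
#' @param n_turns Number of recorded time steps per agent (>= 2). The
#'   recorded series include the initial state at index 0 followed by
#'   \code{n_turns - 1} updates.
#' @param alpha Decay fraction per step, in \[0, 1\]. Each update subtracts
#'   \code{alpha} times the previous behavior, damping runaway growth.
#' @param influence Global receptivity scalar multiplying the context-mediated
#'   coupling; fixed at 1 in the reference conditions.
#' @param noise_low,noise_high Bounds of the uniform noise added independently
#'   to each agent at each step (\code{noise_low < noise_high}).
#' @param init_low,init_high Bounds of the uniform initial-state draw
#'   (\code{init_low <= init_high}).
#' @param start_agent Initialization policy: \code{"both"} draws both initial
#'   states; \code{"agent1"}/\code{"agent2"} draw only that agent's initial
#'   state and set the other to 0 (one agent "starts the conversation").
#' @param seed Non-negative integer master seed.
#' @param update_mode \code{"synchronous"} updates both components at once
#'   from the previous state (the model's displayed two-component map);
#'   \code{"alternating"} updates one component per step while the other
#'   holds its value, alternating agents.
#' @return An object of class \code{"sim_config"} (a named list).
#' @examples
#' sim_config()
#' sim_config(n_turns = 100, seed = 42)
#' @export
sim_config <- function(n_turns = 500L, alpha = 0.1, influence = 1,
                       noise_low = -0.5, noise_high = 0.5,
                       init_low = -0.5, init_high = 0.5,
                       start_agent = c("both", "agent1", "agent2"),
                       seed = 1L,
                       update_mode = c("synchronous", "alternating")) {
  start_agent <- match.arg(start_agent)
  update_mode <- match.arg(update_mode)
  cfg <- list(n_turns = as.integer(n_turns), alpha = alpha,
              influence = influence,
              noise_low = noise_low, noise_high = noise_high,
              init_low = init_low, init_high = init_high,
              start_agent = start_agent, seed = as.integer(seed),
              update_mode = update_mode)
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$n_turns) || cfg$n_turns < 2) stop("n_turns must be >= 2", call. = FALSE)
  if (!num1(cfg$alpha) || cfg$alpha < 0 || cfg$alpha > 1)
    stop("alpha must lie in [0, 1]", call. = FALSE)
  if (!num1(cfg$influence)) stop("influence must be a finite scalar", call. = FALSE)
  if (!num1(cfg$noise_low) || !num1(cfg$noise_high) || cfg$noise_low >= cfg$noise_high)
    stop("need noise_low < noise_high", call. = FALSE)
  if (!num1(cfg$init_low) || !num1(cfg$init_high) || cfg$init_low > cfg$init_high)
    stop("need init_low <= init_high", call. = FALSE)
  if (!num1(cfg$seed) || cfg$seed < 0) stop("seed must be a non-negative integer", call. = FALSE)
  if (!cfg$start_agent %in% c("both", "agent1", "agent2"))
    stop("unknown start_agent", call. = FALSE)
  if (!cfg$update_mode %in% c("synchronous", "alternating"))
    stop("unknown update_mode", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("dyad simulation config\n")
  cat(sprintf("  turns: %d  alpha: %g  influence: %g  mode: %s\n",
              x$n_turns, x$alpha, x$influence, x$update_mode))
  cat(sprintf("  noise: U(%g, %g)  init: U(%g, %g)  start: %s  seed: %d\n",
              x$noise_low, x$noise_high, x$init_low, x$init_high,
              x$start_agent, x$seed))
  invisible(x)
}

#' Read a simulation configuration from JSON or YAML
#'
#' The document's keys mirror the [sim_config()] argument names exactly;
#' missing keys fall back to the defaults.
#'
#' @param path Path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return A \code{sim_config}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported config format: .", ext, call. = FALSE))
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(sim_config, raw)
}

#' Write a simulation configuration
#'
#' @param config A \code{sim_config}.
#' @param path Output path; format chosen by extension (\code{.json},
#'   \code{.yaml}/\code{.yml}).
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml  = yaml::write_yaml(x, path),
    stop("unsupported config format: .", ext, call. = FALSE))
  invisible(path)
}
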
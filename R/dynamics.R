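#' Decayed coupling matrix
#'
#' The linear map applied to the previous behavior vector at every step:
#' \deqn{M = C \cdot I - \alpha \, \mathrm{Id},}
#' where \eqn{C} is the context matrix, \eqn{I} the scalar influence and
#' \eqn{\alpha} the decay fraction.
#'
#' @param context A \code{context_matrix}.
#' @param config A \code{sim_config}.
#' @return A 2x2 numeric matrix.
#' @export
coupling_matrix <- function(context, config = sim_config()) {
  context <- as_context_matrix(context, relaxed = TRUE)
  validate_config(config)
  as.matrix(context) * config$influence - config$alpha * diag(2)
}

#' Spectral radius of the decayed coupling matrix
#'
#' The largest absolute eigenvalue of \eqn{C \cdot I - \alpha\,\mathrm{Id}}.
#' Values above 1 flag contexts whose noise-free dynamics grow exponentially;
#' several ternary contexts are of this kind (up to 2.1 at the defaults), so
#' downstream correlation statistics are computed on rescaled series.
#'
#' @inheritParams coupling_matrix
#' @return A non-negative real number.
#' @examples
#' spectral_radius(context_matrix(1, 1, 1, 1))  # 1.9
#' @export
spectral_radius <- function(context, config = sim_config()) {
  m <- coupling_matrix(context, config)
  max(abs(eigen(m, only.values = TRUE)$values))
}

#' Advance the dyad one step
#'
#' One application of the update rule
#' \deqn{B(t) = (C \cdot I - \alpha\,\mathrm{Id})\, B(t-1) + U,}
#' with \eqn{U} the supplied noise pair. Deterministic given its arguments.
#'
#' @param b_prev Numeric pair: previous behaviors \code{(b1, b2)}.
#' @param context A \code{context_matrix}.
#' @param config A \code{sim_config}.
#' @param noise Numeric pair of noise values, one per agent.
#' @return Numeric pair \code{(b1, b2)} at the next step.
#' @export
step_dyad <- function(b_prev, context, config = sim_config(), noise = c(0, 0)) {
  if (length(b_prev) != 2L || !is.numeric(b_prev) || any(!is.finite(b_prev)))
    stop("invalid state: b_prev must be a pair of finite numbers", call. = FALSE)
  if (length(noise) != 2L || !is.numeric(noise) || any(!is.finite(noise)))
    stop("noise must be a pair of finite numbers", call. = FALSE)
  m <- coupling_matrix(context, config)
  as.vector(m %*% b_prev + noise)
}

#' Simulate one dyadic "conversation"
#'
#' Generates the paired behavior series \code{b1(t)}, \code{b2(t)} for one
#' simulated interaction under a given context matrix. Index 0 of each series
#' holds the initial state; the remaining \code{n_turns - 1} points are
#' produced by repeated application of the update rule with fresh independent
#' uniform noise per agent per step.
#'
#' Randomness is fully reproducible: all draws come from R's RNG seeded with
#' \code{config$seed}, in a fixed order (initial state of agent 1 where drawn,
#' then agent 2 where drawn, then the whole noise block of agent 1, then that
#' of agent 2). Under \code{start_agent = "agent1"}/\code{"agent2"} the
#' non-starting agent's initial state is 0.
#'
#' In \code{update_mode = "alternating"} only one component is updated per
#' step (the other holds its value); the starting agent (agent 1 under
#' \code{"both"}) updates first.
#'
#' @param context A \code{context_matrix}.
#' @param config A \code{sim_config}.
#' @param noise Optional \code{(n_turns - 1) x 2} matrix of noise values
#'   overriding the random draws (column j = agent j). Used for exact
#'   closed-form checks.
#' @param init Optional numeric pair overriding the initial state.
#' @return An object of class \code{"dyad_trajectory"}: a list with numeric
#'   vectors \code{b1}, \code{b2} (length \code{n_turns}), plus
#'   \code{context}, \code{config} and \code{seed_used}.
#' @examples
#' traj <- simulate_dyad(context_matrix(1, 1, 1, 1), sim_config(seed = 7))
#' pearson_r(traj)
#' @export
simulate_dyad <- function(context, config = sim_config(), noise = NULL,
                          init = NULL) {
  context <- as_context_matrix(context,
                               relaxed = isTRUE(attr(context, "relaxed")))
  validate_config(config)
  n <- config$n_turns
  m <- coupling_matrix(context, config)
  m11 <- m[1, 1]; m12 <- m[1, 2]; m21 <- m[2, 1]; m22 <- m[2, 2]

  use_rng <- is.null(noise) || is.null(init)
  if (use_rng) set.seed(config$seed)

  if (is.null(init)) {
    init <- switch(config$start_agent,
      both   = c(stats::runif(1, config$init_low, config$init_high),
                 stats::runif(1, config$init_low, config$init_high)),
      agent1 = c(stats::runif(1, config$init_low, config$init_high), 0),
      agent2 = c(0, stats::runif(1, config$init_low, config$init_high)))
  } else if (length(init) != 2L || !is.numeric(init) || any(!is.finite(init))) {
    stop("init must be a pair of finite numbers", call. = FALSE)
  }
  if (is.null(noise)) {
    e1 <- stats::runif(n - 1, config$noise_low, config$noise_high)
    e2 <- stats::runif(n - 1, config$noise_low, config$noise_high)
  } else {
    noise <- as.matrix(noise)
    if (nrow(noise) != n - 1 || ncol(noise) != 2L)
      stop("noise must be an (n_turns - 1) x 2 matrix", call. = FALSE)
    e1 <- noise[, 1]; e2 <- noise[, 2]
  }

  b1 <- numeric(n); b2 <- numeric(n)
  b1[1] <- init[1]; b2[1] <- init[2]
  if (config$update_mode == "synchronous") {
    for (t in 2:n) {
      b1[t] <- m11 * b1[t - 1] + m12 * b2[t - 1] + e1[t - 1]
      b2[t] <- m21 * b1[t - 1] + m22 * b2[t - 1] + e2[t - 1]
    }
  } else {
    first <- if (config$start_agent == "agent2") 2L else 1L
    for (t in 2:n) {
      who <- if ((t + first) %% 2L == 1L) 1L else 2L
      if (who == 1L) {
        b1[t] <- m11 * b1[t - 1] + m12 * b2[t - 1] + e1[t - 1]
        b2[t] <- b2[t - 1]
      } else {
        b2[t] <- m21 * b1[t - 1] + m22 * b2[t - 1] + e2[t - 1]
        b1[t] <- b1[t - 1]
      }
    }
  }
  structure(list(b1 = b1, b2 = b2, context = context, config = config,
                 seed_used = config$seed),
            class = "dyad_trajectory")
}

#' @export
print.dyad_trajectory <- function(x, ...) {
  cat(sprintf("dyad trajectory: %d turns, C = (%g, %g; %g, %g), seed %d\n",
              length(x$b1), x$context$s1, x$context$o1, x$context$o2,
              x$context$s2, x$seed_used))
  invisible(x)
}

#' Export a trajectory as CSV plus JSON sidecar
#'
#' Writes a comma-separated file with header \code{turn,b1,b2} (turn indexed
#' from 0) and a \code{<path>.json} sidecar carrying the context entries,
#' the full configuration and the seed used.
#'
#' @param traj A \code{dyad_trajectory}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "dyad_trajectory"))
  df <- data.frame(turn = seq_along(traj$b1) - 1L, b1 = traj$b1, b2 = traj$b2)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(context = unclass(traj$context)[c("s1", "o1", "o2", "s2")],
               config = unclass(traj$config), seed_used = traj$seed_used)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a two-channel behavior series from CSV
#'
#' Accepts the dialect written by [write_trajectory()] (header
#' \code{turn,b1,b2}); any extra columns are ignored. If the JSON sidecar is
#' present the context and configuration are restored, otherwise a minimal
#' trajectory (suitable for the metrics functions) is returned.
#'
#' @param path CSV path.
#' @return A \code{dyad_trajectory}.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("b1", "b2") %in% names(df)))
    stop("malformed series CSV (need columns b1 and b2): ", path, call. = FALSE)
  side_path <- paste0(path, ".json")
  context <- config <- NULL
  seed_used <- NA_integer_
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    context <- as_context_matrix(side$context,
                                 relaxed = !all(unlist(side$context) %in% c(-1, 0, 1)))
    cfg <- side$config[names(side$config) %in% names(formals(sim_config))]
    config <- do.call(sim_config, cfg)
    seed_used <- side$seed_used
  }
  structure(list(b1 = df$b1, b2 = df$b2, context = context, config = config,
                 seed_used = seed_used),
            class = "dyad_trajectory")
}
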
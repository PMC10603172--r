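#' Child seed for one sweep run
#'
#' The sweep derives one child seed per (context, repetition) pair from the
#' master seed through a fixed counter scheme,
#' \code{(master + counter * 1000003) mod 2147483629},
#' so any single run can be reproduced in isolation. The modulus is a prime
#' below 2^31; counters are 1-based in row order (context index varying
#' slowest).
#'
#' @param master_seed Non-negative integer master seed.
#' @param counter Positive integer run counter.
#' @return An integer seed.
#' @export
child_seed <- function(master_seed, counter) {
  as.integer((as.double(master_seed) + as.double(counter) * 1000003) %% 2147483629)
}

#' Run the exhaustive context sweep
#'
#' Simulates \code{reps} independent "conversations" for every context in
#' \code{contexts} (by default all 81 ternary matrices) and records the
#' per-run Pearson correlation between the two behavior series, computed on
#' max-abs rescaled series (see [pearson_r()]). With the defaults
#' (81 contexts x 100 repetitions x 500 turns) this reproduces the reference
#' 8100-run experiment.
#'
#' Runs whose correlation is undefined (a constant series, or non-finite
#' values under non-default configurations) are retained with \code{r = NA};
#' their count is reported via \code{message()}.
#'
#' @param config A \code{sim_config}; \code{config$seed} is the master seed.
#' @param reps Repetitions per context (>= 1).
#' @param contexts Data frame of contexts (columns \code{s1, o1, o2, s2});
#'   defaults to [enumerate_contexts()].
#' @return A data frame of class \code{"dyad_sweep"} with columns
#'   \code{s1, o1, o2, s2, rep, seed, r} and \code{nrow(contexts) * reps}
#'   rows; attributes \code{master_seed} and \code{config} carry provenance.
#' @examples
#' sw <- run_sweep(sim_config(n_turns = 50, seed = 1), reps = 2,
#'                 contexts = enumerate_contexts()[1:3, ])
#' nrow(sw)  # 6
#' @export
run_sweep <- function(config = sim_config(), reps = 100L,
                      contexts = enumerate_contexts()) {
  validate_config(config)
  reps <- as.integer(reps)
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  if (!all(c("s1", "o1", "o2", "s2") %in% names(contexts)))
    stop("contexts must have columns s1, o1, o2, s2", call. = FALSE)

  n_ctx <- nrow(contexts)
  total <- n_ctx * reps
  seeds <- child_seed(config$seed, seq_len(total))
  r <- numeric(total)
  run_cfg <- config
  k <- 0L
  for (i in seq_len(n_ctx)) {
    ctx <- context_matrix(contexts$s1[i], contexts$o1[i],
                          contexts$o2[i], contexts$s2[i])
    for (rep in seq_len(reps)) {
      k <- k + 1L
      run_cfg$seed <- seeds[k]
      traj <- simulate_dyad(ctx, run_cfg)
      r[k] <- if (all(is.finite(traj$b1)) && all(is.finite(traj$b2)))
        pearson_r(traj) else NA_real_
    }
  }
  out <- data.frame(contexts[rep(seq_len(n_ctx), each = reps),
                             c("s1", "o1", "o2", "s2")],
                    rep = rep(seq_len(reps) - 1L, times = n_ctx),
                    seed = seeds, r = r)
  rownames(out) <- NULL
  n_missing <- sum(is.na(r))
  if (n_missing > 0)
    message(sprintf("sweep: %d of %d runs had undefined r", n_missing, total))
  structure(out, master_seed = config$seed, config = config,
            class = c("dyad_sweep", "data.frame"))
}

#' Write a sweep table as CSV plus JSON sidecar
#'
#' Header \code{s1,o1,o2,s2,rep,seed,r}; missing \code{r} written as an empty
#' field. The sidecar \code{<path>.json} records the master seed and the full
#' configuration.
#'
#' @param sweep A \code{dyad_sweep}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(is.data.frame(sweep))
  utils::write.csv(sweep, path, row.names = FALSE, quote = FALSE, na = "")
  side <- list(master_seed = attr(sweep, "master_seed"),
               config = unclass(attr(sweep, "config")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a sweep table written by [write_sweep()]
#'
#' @param path CSV path.
#' @return A \code{dyad_sweep} data frame (empty \code{r} fields become
#'   \code{NA}).
#' @export
read_sweep <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, na.strings = ""),
                 error = function(e) stop("malformed sweep CSV: ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  need <- c("s1", "o1", "o2", "s2", "rep", "seed", "r")
  if (!all(need %in% names(df)) || nrow(df) == 0L)
    stop("malformed sweep CSV (need header s1,o1,o2,s2,rep,seed,r and rows): ",
         path, call. = FALSE)
  side_path <- paste0(path, ".json")
  master_seed <- NA_integer_; config <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    master_seed <- side$master_seed
    cfg <- side$config[names(side$config) %in% names(formals(sim_config))]
    config <- do.call(sim_config, cfg)
  }
  structure(df[, need], master_seed = master_seed, config = config,
            class = c("dyad_sweep", "data.frame"))
}
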
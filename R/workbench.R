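# Sweep results are plain tibbles with a light class and metadata attributes
# (experiment name, config echo, seed, trial count) so they can round-trip
# through CSV: the data are the columns, the metadata go to a JSON sidecar.
new_sweep <- function(tbl, experiment, config = NULL, seed = NULL,
                      n_trials = NULL) {
  structure(as_tibble(tbl),
            class = c("olf_sweep", class(as_tibble(tbl))),
            experiment = experiment,
            config = config, seed = seed, n_trials = n_trials)
}

# FNV-1a hash of a string, reported as 8 hex digits; used to stamp outputs
# with a config fingerprint without adding a dependency.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                        null = "null", force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) # keep in integer range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Experiment configuration
#'
#' Validated bundle of parameters for [run_experiment()]. Unknown fields are
#' rejected so a misspelled grid name cannot silently fall back to a default.
#'
#' @param experiment One of `"p_false_sweep"`, `"m_sweep"`, `"theta_sweep"`,
#'   `"robustness"`, `"lasso_compare"`, `"limits_table"`.
#' @param ... Named experiment parameters; see Details.
#' @details Common fields: `N`, `M`, `K`, `p`, `theta_r`, `n_trials`, `seed`.
#'   Grids: `p_grid` (p_false_sweep), `M_grid` (m_sweep), `theta_r_grid`
#'   (theta_sweep), `K_grid` (lasso_compare, limits_table),
#'   `stuck_on_grid` (robustness). Other: `beta`, `n_reps`, `iter_cap`
#'   (lasso_compare); `snr_ref` (limits_table); `false_negative_rate`
#'   (theta_sweep).
#' @return An object of class `experiment_config`.
#' @export
#' @examples
#' experiment_config("p_false_sweep", M = 500, K = 15,
#'                   p_grid = seq(0.02, 0.3, by = 0.02))
experiment_config <- function(experiment, ...) {
  allowed <- list(
    p_false_sweep = c("M", "K", "p_grid"),
    m_sweep = c("N", "K", "M_grid", "theta_r", "n_trials", "seed"),
    theta_sweep = c("N", "M", "K", "p", "theta_r_grid", "n_trials",
                    "false_negative_rate", "seed"),
    robustness = c("N", "M", "K", "p", "stuck_on_grid", "n_trials", "seed"),
    lasso_compare = c("N", "M", "beta", "K_grid", "n_reps", "iter_cap",
                      "max_iter", "seed"),
    limits_table = c("N", "K_grid", "snr_ref"))
  if (!experiment %in% names(allowed)) {
    abort(sprintf("unknown experiment '%s'", experiment),
          class = "olfcs_unknown_experiment")
  }
  fields <- list(...)
  bad <- setdiff(names(fields), allowed[[experiment]])
  if (length(bad)) {
    abort(sprintf("unknown field(s) for %s: %s", experiment,
                  paste(bad, collapse = ", ")),
          class = "olfcs_invalid_config")
  }
  for (g in intersect(names(fields), c("p_grid", "M_grid", "theta_r_grid",
                                       "K_grid", "stuck_on_grid"))) {
    if (length(fields[[g]]) == 0) {
      abort(sprintf("%s must be non-empty", g), class = "olfcs_invalid_config")
    }
  }
  structure(c(list(experiment = experiment), fields),
            class = "experiment_config")
}

#' Read / write an experiment configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_experiment_config()` returns an [experiment_config()];
#'   `write_experiment_config()` returns `path` invisibly.
#' @export
read_experiment_config <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(lst$experiment)) {
    abort("config JSON must contain an 'experiment' field",
          class = "olfcs_invalid_config")
  }
  do.call(experiment_config, lst)
}

#' @rdname read_experiment_config
#' @param config An [experiment_config()].
#' @export
write_experiment_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run a named experiment and (optionally) persist its results
#'
#' Dispatches to the sweep implementations and, when `out_dir` is given,
#' writes `<experiment>.csv` (RFC 4180, via readr) plus
#' `<experiment>_meta.json` carrying the config echo, seed, config hash and
#' package version. Given the same config and seed the run is deterministic,
#' down to byte-identical CSV output.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return The result tibble (class `olf_sweep`), invisibly carrying its
#'   metadata attributes.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  cfg <- config
  res <- switch(
    cfg$experiment,
    p_false_sweep = {
      stopifnot(!is.null(cfg$M), !is.null(cfg$K), !is.null(cfg$p_grid))
      new_sweep(
        tibble(p = cfg$p_grid,
               p_false_exact = p_false_exact(cfg$p_grid, cfg$K, cfg$M),
               p_false_approx = p_false_approx(cfg$p_grid, cfg$K, cfg$M)),
        experiment = "p_false_sweep", config = cfg)
    },
    m_sweep = {
      base <- model_config(cfg$N, max(cfg$M_grid), cfg$K,
                           optimal_connectivity(cfg$K),
                           theta_r = cfg$theta_r %||% 1)
      m_sweep(base, cfg$M_grid, cfg$n_trials, seed = cfg$seed)
    },
    theta_sweep = {
      base <- model_config(cfg$N, cfg$M, cfg$K,
                           cfg$p %||% optimal_connectivity(cfg$K))
      threshold_sweep(base, cfg$theta_r_grid, cfg$n_trials,
                      noise = noise_spec(false_negative_rate =
                                           cfg$false_negative_rate %||% 0),
                      seed = cfg$seed)
    },
    robustness = {
      base <- model_config(cfg$N, cfg$M, cfg$K,
                           cfg$p %||% optimal_connectivity(cfg$K))
      rows <- purrr::imap(cfg$stuck_on_grid, function(fr, i) {
        est <- estimate_p_false(base, cfg$n_trials,
                                noise = noise_spec(stuck_on_fraction = fr),
                                seed = if (!is.null(cfg$seed))
                                  child_seed(cfg$seed, i) else NULL)
        tibble(stuck_on_fraction = fr, p_false = est$mean,
               p_false_se = est$se)
      })
      new_sweep(dplyr::bind_rows(rows), "robustness", config = cfg,
                seed = cfg$seed, n_trials = cfg$n_trials)
    },
    lasso_compare = compare_architectures(
      N = cfg$N %||% 1000, M = cfg$M %||% 500, beta = cfg$beta %||% 0.001,
      K_grid = cfg$K_grid, n_reps = cfg$n_reps %||% 100,
      iter_cap = cfg$iter_cap, max_iter = cfg$max_iter %||% 1000L,
      seed = cfg$seed),
    limits_table = limits_table(cfg$N, cfg$K_grid,
                                snr_ref = cfg$snr_ref %||% 10))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(out_dir, paste0(cfg$experiment, ".csv"))
    readr::write_csv(res, csv)
    meta <- list(config = unclass(cfg), config_hash = config_hash(cfg),
                 seed = cfg$seed,
                 package_version = as.character(utils::packageVersion("olfcs")))
    jsonlite::write_json(meta, file.path(out_dir, paste0(cfg$experiment, "_meta.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a matrix in Matrix Market coordinate format
#'
#' Thin wrappers over `Matrix::writeMM()`/`Matrix::readMM()` with a header
#' check: binary and real sparse matrices round-trip exactly (equal nonzero
#' sets and values), including the empty (all-zero) matrix.
#'
#' @param m Matrix (base or Matrix); coerced to sparse for writing.
#' @param path Destination `.mtx` path.
#' @return `save_matrix()` returns `path` invisibly; `load_matrix()` returns
#'   a `Matrix::dgCMatrix`.
#' @export
save_matrix <- function(m, path) {
  if (!inherits(m, "Matrix")) m <- Matrix::Matrix(m, sparse = TRUE)
  m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, path)
  invisible(path)
}

#' @rdname save_matrix
#' @export
load_matrix <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("^%%MatrixMarket[ \t]+matrix[ \t]+coordinate", header)) {
    abort(sprintf("malformed Matrix Market header at line 1 of '%s': %s",
                  path, header),
          class = "olfcs_parse_error")
  }
  # readMM may return pattern/symmetric triplet classes; normalize to dgC
  as(as(as(Matrix::readMM(path), "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

#' Compression-limit table
#'
#' For each sparsity `K`: the information-theoretic floor `M_min` on the
#' number of binary measurements, the corresponding exact and asymptotic
#' compression ratios, the ratio `alpha_SNR` the codec needs at a reference
#' SNR, and `alpha_snr / alpha_min`. As `f = K/N` decreases the last column
#' trends (slowly, logarithmically) toward the limiting factor
#' `e ln 2 = 1.8842`: the codec needs about twice the theoretically minimal
#' number of measurements. Rows with `K = N` have `M_min = 0` (a single
#' possible message) and undefined ratios.
#'
#' @param N Signal dimension.
#' @param K_grid Sparsities to tabulate.
#' @param snr_ref Reference SNR for `alpha_snr` (default 10).
#' @return A tibble of class `olf_sweep`: `K`, `f`, `m_min`, `alpha_exact`,
#'   `alpha_min`, `alpha_snr`, `ratio`.
#' @export
#' @examples
#' limits_table(10000, K_grid = c(1, 3, 10, 30))
limits_table <- function(N, K_grid, snr_ref = 10) {
  stopifnot(length(K_grid) >= 1, all(K_grid >= 0), all(K_grid <= N))
  f <- K_grid / N
  ok <- f > 0 & f < 1
  amin <- asnr <- rep(NA_real_, length(f))
  amin[ok] <- alpha_min_asymptotic(f[ok])
  asnr[ok] <- alpha_snr(f[ok], snr_ref)
  mm <- min_bits(N, K_grid)
  new_sweep(
    tibble(K = K_grid, f = f, m_min = mm, alpha_exact = mm / N,
           alpha_min = amin, alpha_snr = asnr, ratio = asnr / amin),
    experiment = "limits_table",
    config = list(N = N, snr_ref = snr_ref))
}
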
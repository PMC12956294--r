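#' Default pipeline configuration
#'
#' Bundles every tunable of the pipeline with its default: a 45 s
#' rectangular window advanced 1 TR at a time with static-term demeaning;
#' automatic model-order selection (or a fixed `K`, 15 at full imaging
#' scale); a 0.8 closeness constraint with 10 refinement iterations;
#' strong-state threshold 0.06; percentile (25/75) convergence thresholds;
#' 50 SDP bins; FDR level 0.05; k = 3 histogram clusters.
#'
#' @param window_seconds Window length in seconds (used with `tr_seconds`).
#' @param window_len_tr Window length in TRs; overrides `window_seconds`.
#' @param step_tr Window step in TRs.
#' @param demean Remove the static term per pair.
#' @param K Number of states, or `NULL` to select by scree elbow.
#' @param max_order Largest order considered by the elbow criterion.
#' @param seed Seed for ICA and clustering.
#' @param rho Back-reconstruction closeness constraint in (0, 1].
#' @param refine_iters Constrained refinement iterations.
#' @param thr Strong-state amplitude threshold.
#' @param eps_probs Percentiles for the (epsilon, theta) thresholds.
#' @param sdp_bins Number of shared SDP bins.
#' @param q FDR level for group comparisons.
#' @param var_equal Pooled-variance (Student) t-test when `TRUE`.
#' @param kmeans_k,kmeans_restarts Histogram clustering parameters.
#' @param tr_seconds Repetition time, used to convert `window_seconds`.
#' @param input Whether manifest paths hold raw timecourses
#'   (`"timecourses"`, default: windowing is applied) or precomputed
#'   windowed-FNC matrices (`"wfnc"`: windowing is skipped).
#' @param residualize Regress age/sex/site out of every derived metric
#'   feature (per cohort) before the group tests, when those columns are
#'   present in the manifest.
#' @return A `cddfip_config` list.
#' @export
ddfip_config <- function(window_seconds = 45, window_len_tr = NULL,
                         step_tr = 1L, demean = TRUE, K = NULL,
                         max_order = 30L, seed = 42L, rho = 0.8,
                         refine_iters = 10L, thr = 0.06,
                         eps_probs = c(0.25, 0.75), sdp_bins = 50L,
                         q = 0.05, var_equal = TRUE, kmeans_k = 3L,
                         kmeans_restarts = 10L, tr_seconds = 2,
                         input = c("timecourses", "wfnc"),
                         residualize = TRUE) {
  input <- match.arg(input)
  cfg <- list(
    window_seconds = window_seconds, window_len_tr = window_len_tr,
    step_tr = step_tr, demean = demean, K = K, max_order = max_order,
    seed = seed, rho = rho, refine_iters = refine_iters, thr = thr,
    eps_probs = eps_probs, sdp_bins = sdp_bins, q = q,
    var_equal = var_equal, kmeans_k = kmeans_k,
    kmeans_restarts = kmeans_restarts, tr_seconds = tr_seconds,
    input = input, residualize = residualize
  )
  class(cfg) <- "cddfip_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [ddfip_config()]; unknown keys are rejected
#' so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A `cddfip_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the `yaml` package is required to read config files.")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(ddfip_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "cddfip_io_error")
  }
  do.call(ddfip_config, vals)
}

# short deterministic hash of the configuration, for provenance stamps
config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 12), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            0xFFFFFFF)
}

#' Run the full pipeline on a cohort
#'
#' Executes windowing (for timecourse-level input), static-term demeaning,
#' group-state estimation, constrained back-reconstruction with calibration,
#' dynamics metrics, and two-group statistics, writing every artifact as a
#' provenance-stamped TSV/CSV when `out_dir` is given. Re-running with the
#' same inputs and config reproduces identical numbers.
#'
#' @param x A `cddfip_cohort` from [simulate_cohort()], or a manifest tibble
#'   from [read_manifest()] whose paths hold timecourse TSVs.
#' @param config A `cddfip_config`.
#' @param out_dir Optional output directory.
#' @return A `cddfip_results` list: `basis`, `decompositions`, `thresholds`,
#'   `dynamics` (per subject), `metrics` (tidy long tibble), `comparisons`
#'   (list of `cddfip_comparison`), `clustering`, `config`, `manifest`.
#' @export
run_pipeline <- function(x, config = ddfip_config(), out_dir = NULL) {
  stopifnot(inherits(config, "cddfip_config"))
  stage <- "input"
  res <- tryCatch({
    if (inherits(x, "cddfip_cohort")) {
      manifest <- x$manifest
      stage <- "window"
      wfnc <- lapply(x$subjects, function(s) {
        obs <- s$observed
        if (inherits(obs, "cddfip_timecourses")) {
          wl <- config$window_len_tr %||%
            window_len_from_seconds(config$window_seconds, config$tr_seconds)
          obs <- sliding_window_fnc(obs, wl, config$step_tr)
        }
        if (config$demean) demean_static(obs) else obs
      })
    } else {
      manifest <- x
      stage <- "window"
      wfnc <- lapply(seq_len(nrow(manifest)), function(i) {
        tc <- read_timecourses(manifest$path[i],
                               tr_seconds = config$tr_seconds,
                               subject_id = manifest$subject_id[i])
        w <- if (identical(config$input, "wfnc")) {
          as_wfnc(tc$values)  # file already holds W x P windowed FNC
        } else {
          wl <- config$window_len_tr %||%
            window_len_from_seconds(config$window_seconds, config$tr_seconds)
          sliding_window_fnc(tc, wl, config$step_tr)
        }
        if (config$demean) demean_static(w) else w
      })
    }

    stage <- "fit-group"
    concat <- stack_wfnc(wfnc)
    order_sel <- NULL
    K <- config$K
    if (is.null(K)) {
      order_sel <- select_model_order(concat,
                                      min(config$max_order, dim(concat) - 1L))
      K <- order_sel$order
    }
    basis <- fit_group_ddfips(concat, K = K, seed = config$seed)

    stage <- "fit-subjects"
    decomps <- fit_subjects(wfnc, basis, rho = config$rho,
                            refine_iters = config$refine_iters)

    stage <- "metrics"
    dists <- lapply(decomps, function(d)
      pairwise_amplitude_distance(d$calibrated_mixing))
    pool <- unlist(lapply(dists, pool_distances))
    thresholds <- select_epsilon_theta(pool, probs = config$eps_probs)
    edges <- sdp_bin_edges(pool, config$sdp_bins)
    dynamics <- lapply(decomps, function(d)
      compute_dynamics(d$calibrated_mixing, thresholds$epsilon,
                       thresholds$theta, edges, thr = config$thr))
    metrics <- tidy_dynamics(dynamics, manifest$subject_id)

    stage <- "stats"
    comparisons <- NULL
    clustering <- NULL
    if (length(unique(manifest$group)) == 2) {
      comparisons <- compare_cohort_groups(dynamics, manifest,
                                           q = config$q,
                                           var_equal = config$var_equal,
                                           residualize = isTRUE(config$residualize))
    }
    H <- do.call(rbind, lapply(dynamics, function(d) d$density$pdf$probability))
    if (nrow(H) >= config$kmeans_k) {
      clustering <- kmeans_histograms(H, k = config$kmeans_k,
                                      seed = config$seed,
                                      restarts = config$kmeans_restarts)
    }

    structure(
      list(basis = basis, order_selection = order_sel,
           decompositions = decomps, thresholds = thresholds,
           sdp_bin_edges = edges, dynamics = dynamics, metrics = metrics,
           comparisons = comparisons, clustering = clustering,
           config = config, manifest = manifest),
      class = "cddfip_results"
    )
  }, error = function(e) {
    abort(sprintf("pipeline failed at stage `%s`: %s", stage,
                  conditionMessage(e)),
          class = "cddfip_pipeline_error", parent = e)
  })
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' @export
print.cddfip_results <- function(x, ...) {
  cat(sprintf(
    "<pipeline results: %d subjects, K = %d states, epsilon = %.4g, theta = %.4g>\n",
    length(x$decompositions), x$basis$K, x$thresholds$epsilon,
    x$thresholds$theta
  ))
  invisible(x)
}

# long tidy table of every per-subject metric
tidy_dynamics <- function(dynamics, subject_ids) {
  purrr::map2_dfr(dynamics, subject_ids, function(d, id) {
    N <- nrow(d$converged_fraction)
    ut <- which(upper.tri(d$converged_fraction), arr.ind = TRUE)
    pair_lab <- sprintf("%d-%d", ut[, 1], ut[, 2])
    dplyr::bind_rows(
      tibble::tibble(subject_id = id, metric = "occupancy",
                     index = as.character(d$occupancy$state),
                     value = d$occupancy$percent),
      tibble::tibble(subject_id = id, metric = "converged_fraction",
                     index = pair_lab,
                     value = d$converged_fraction[upper.tri(d$converged_fraction)]),
      tibble::tibble(subject_id = id, metric = "diverged_fraction",
                     index = pair_lab,
                     value = d$diverged_fraction[upper.tri(d$diverged_fraction)]),
      tibble::tibble(subject_id = id, metric = "sdp",
                     index = as.character(d$sdp$bin), value = d$sdp$density),
      tibble::tibble(subject_id = id, metric = "density_pdf",
                     index = as.character(d$density$pdf$k),
                     value = d$density$pdf$probability)
    )
  })
}

# two-group comparisons over the standard metric families; covariates
# (age, sex, site) are regressed out of each feature across the cohort
# before testing when requested and available
compare_cohort_groups <- function(dynamics, manifest, q = 0.05,
                                  var_equal = TRUE, residualize = TRUE) {
  groups <- sort(unique(manifest$group))
  ia <- manifest$group == groups[1]
  ib <- manifest$group == groups[2]
  if (sum(ia) < 2 || sum(ib) < 2) return(NULL)
  cov_cols <- intersect(c("age", "sex", "site"), names(manifest))
  # single-level factors carry no information and would break the design
  cov_cols <- cov_cols[vapply(manifest[cov_cols],
                              function(v) length(unique(v)) > 1,
                              logical(1))]
  cov_ok <- residualize && length(cov_cols) > 0
  ut_vec <- function(m) m[upper.tri(m)]
  fam <- function(f, names) {
    Mall <- do.call(rbind, lapply(dynamics, f))
    if (cov_ok) {
      Mall <- suppressWarnings(
        residualize_covariates(Mall, manifest[cov_cols])
      )
    }
    compare_groups(Mall[ia, , drop = FALSE], Mall[ib, , drop = FALSE],
                   q_threshold = q, var_equal = var_equal,
                   feature_names = names)
  }
  N <- nrow(dynamics[[1]]$converged_fraction)
  ut <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  pair_lab <- sprintf("%d-%d", ut[, 1], ut[, 2])
  list(
    converged = fam(function(d) ut_vec(d$converged_fraction), pair_lab),
    diverged = fam(function(d) ut_vec(d$diverged_fraction), pair_lab),
    occupancy = fam(function(d) d$occupancy$percent,
                    paste0("state", seq_len(nrow(dynamics[[1]]$occupancy)))),
    density = fam(function(d) d$density$pdf$probability,
                  paste0("k", seq_along(dynamics[[1]]$density$pdf$k) - 1L)),
    sdp = fam(function(d) d$sdp$density,
              paste0("bin", seq_along(dynamics[[1]]$sdp$density)))
  )
}

# write all result tables under out_dir with provenance stamps
write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- sprintf("cddfip config=%s seed=%d", config_hash(res$config),
                  res$config$seed)
  write_matrix_tsv(res$basis$states, file.path(out_dir, "basis_states.tsv"),
                   prov)
  readr::write_csv(res$metrics, file.path(out_dir, "metrics_long.csv"))
  readr::write_csv(res$manifest, file.path(out_dir, "manifest.csv"))
  for (i in seq_along(res$decompositions)) {
    write_matrix_tsv(res$decompositions[[i]]$calibrated_mixing,
                     file.path(out_dir, sprintf("mixing_%s.tsv",
                                                res$manifest$subject_id[i])),
                     prov)
  }
  if (!is.null(res$comparisons)) {
    for (nm in names(res$comparisons)) {
      readr::write_csv(res$comparisons[[nm]],
                       file.path(out_dir, sprintf("comparison_%s.csv", nm)))
    }
  }
  if (!is.null(res$clustering)) {
    readr::write_csv(
      tibble::tibble(subject_id = res$manifest$subject_id,
                     cluster = res$clustering$labels),
      file.path(out_dir, "clusters.csv")
    )
  }
  invisible(out_dir)
}
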
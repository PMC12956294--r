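#' Generate ground-truth connectivity states
#'
#' Builds `K` block-structured connectivity states over `M` networks. The
#' networks are partitioned into communities and each state loads on its own
#' community-pair block (plus small dense jitter), which makes the states
#' nearly uncorrelated by construction; candidates are redrawn until every
#' pairwise absolute row correlation is at most 0.3. Rows are unit L2 norm
#' and each devectorized state is symmetric with zero diagonal.
#'
#' @param K Number of states (>= 1, at most `M(M-1)/2`).
#' @param M Number of networks (>= 3).
#' @param seed Integer seed; the result is a deterministic function of
#'   `(K, M, seed)`.
#' @param jitter_sd Standard deviation of the dense Gaussian jitter added on
#'   top of the block loading (relative to a block loading of 1).
#' @return A `cddfip_states` object: list with `states` (`K x P` matrix,
#'   unit-norm rows), `n_networks`, `block_structure` (list of community-pair
#'   index sets), `seed`.
#' @export
#' @examples
#' gt <- make_states(K = 3, M = 10, seed = 1)
#' range(rowSums(gt$states^2)) # unit norm
make_states <- function(K, M, seed, jitter_sd = 0.1) {
  K <- as.integer(K); M <- as.integer(M)
  if (K < 1L) abort("`K` must be >= 1.", class = "cddfip_param_error")
  if (M < 3L) abort("`M` must be >= 3.", class = "cddfip_param_error")
  P <- n_pairs(M)
  if (K > P) {
    abort(sprintf("K = %d exceeds the number of connectivity pairs P = %d.",
                  K, P),
          class = "cddfip_infeasible_basis_error")
  }
  # smallest number of communities G whose G(G+1)/2 blocks cover K states
  G <- 1L
  while (G * (G + 1L) / 2L < K || (G == 1L && K > 1L)) G <- G + 1L
  G <- min(G, M)
  community <- sort(rep(seq_len(G), length.out = M))
  # enumerate community-pair blocks (within- and between-community)
  blocks <- list()
  for (a in seq_len(G)) for (b in a:G) blocks[[length(blocks) + 1L]] <- c(a, b)
  # vectorize_upper is row-major; build a lookup from (i,j) to vector position
  pos <- matrix(0L, M, M)
  p <- 0L
  for (i in seq_len(M - 1L)) for (j in (i + 1L):M) { p <- p + 1L; pos[i, j] <- p }

  block_members <- lapply(blocks, function(ab) {
    ii <- which(community == ab[1])
    jj <- which(community == ab[2])
    out <- integer(0)
    for (i in ii) for (j in jj) if (i < j) out <- c(out, pos[i, j])
    sort(unique(out))
  })
  usable <- which(lengths(block_members) > 0L)
  if (length(usable) < K) usable <- rep(usable, length.out = K)

  set.seed(as.integer(seed) %% .Machine$integer.max)
  states <- matrix(0, K, P)
  structure_idx <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- block_members[[usable[((k - 1L) %% length(usable)) + 1L]]]
    ok <- FALSE
    for (attempt in 1:50) {
      # random-sign block loadings keep each state zero-mean and sparse
      # (disjoint supports then give near-orthogonal, separable sources)
      v <- rnorm(P, sd = jitter_sd)
      v[idx] <- v[idx] + sample(c(-1, 1), length(idx), replace = TRUE)
      v <- v / sqrt(sum(v^2))
      if (k == 1L) { ok <- TRUE } else {
        cc <- abs(cor(t(states[seq_len(k - 1L), , drop = FALSE]), v))
        ok <- all(cc <= 0.3)
      }
      if (ok) break
    }
    if (!ok) {
      abort("could not draw a state with pairwise |correlation| <= 0.3.",
            class = "cddfip_infeasible_basis_error")
    }
    states[k, ] <- v
    structure_idx[[k]] <- idx
  }
  structure(
    list(states = states, n_networks = M, block_structure = structure_idx,
         seed = as.integer(seed)),
    class = "cddfip_states"
  )
}

# smooth, standardized mixing timecourse: moving-average filtered white noise
smooth_mixing <- function(W, span) {
  span <- max(2L, as.integer(span))
  x <- rnorm(W + span)
  x <- as.numeric(stats::filter(x, rep(1 / span, span), sides = 1))
  x <- x[!is.na(x)][seq_len(W)]
  (x - mean(x)) / sd(x)
}

#' Simulate one subject at the windowed-FNC level
#'
#' Observed windowed connectivity is a noisy linear mixture of the subject's
#' own states: `observed = A %*% S_subj + E`. Subject states are the
#' ground-truth states plus iid Gaussian perturbation (row-renormalized to
#' unit L2); mixing rows are smooth (moving-average filtered noise, span
#' `ceiling(W/10)`, min 2) with per-state amplitude scales; `E` is white
#' noise with variance `var(signal)/snr`.
#'
#' @param states A `cddfip_states` object.
#' @param W Number of windows (>= 2).
#' @param snr Signal-to-noise variance ratio (> 0; `Inf` for noiseless).
#' @param perturb_sd Per-entry sd of the subject-specific state perturbation.
#' @param seed Integer seed.
#' @param amp_scale_range Per-state amplitude scale profile endpoints
#'   (linear ramp over states); the default gives every state the same unit
#'   scale so states are a priori exchangeable.
#' @return A `cddfip_subject_sim` list: `observed` (demeaned-scale `W x P`
#'   matrix wrapped as a `cddfip_wfnc`), `true_mixing` (`W x K`),
#'   `true_states` (`K x P`), `seed`.
#' @export
simulate_subject_dfnc <- function(states, W, snr, perturb_sd, seed,
                                  amp_scale_range = c(1, 1)) {
  stopifnot(inherits(states, "cddfip_states"))
  W <- as.integer(W)
  if (W < 2L) abort("`W` must be >= 2.", class = "cddfip_param_error")
  if (!is.infinite(snr) && snr <= 0) {
    abort("`snr` must be positive.", class = "cddfip_param_error")
  }
  S0 <- states$states
  K <- nrow(S0); P <- ncol(S0)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  # perturb_sd is the expected L2 distortion of a unit-norm state row, so a
  # per-entry sd of perturb_sd/sqrt(P) gives a perturbation of norm ~perturb_sd
  S <- S0 + matrix(rnorm(K * P, sd = perturb_sd / sqrt(P)), K, P)
  S <- S / sqrt(rowSums(S^2))
  # fixed per-state amplitude profile, shared across subjects, so that
  # between-subject amplitude variance reflects dynamics (and any planted
  # group effect), not an arbitrary per-subject rescaling
  scales <- seq(amp_scale_range[1], amp_scale_range[2], length.out = K)
  A <- vapply(seq_len(K), function(k) {
    smooth_mixing(W, ceiling(W / 10)) * scales[k]
  }, numeric(W))
  signal <- A %*% S
  if (is.infinite(snr)) {
    E <- matrix(0, W, P)
  } else {
    E <- matrix(rnorm(W * P, sd = sqrt(var(as.numeric(signal)) / snr)), W, P)
  }
  observed <- structure(
    list(values = signal + E, window_len_tr = NA_integer_, step_tr = 1L,
         demeaned = FALSE, static_fnc = NULL, n_networks = states$n_networks),
    class = "cddfip_wfnc"
  )
  structure(
    list(observed = observed, true_mixing = A, true_states = S,
         level = "wfnc", seed = as.integer(seed)),
    class = "cddfip_subject_sim"
  )
}

#' Simulate one subject at the raw-timecourse level
#'
#' Samples network timecourses from a slowly drifting covariance
#' `C(t) = corr_repair(sum_k a_k(t) * devec(state_k) + lambda * I)` where the
#' amplitudes `a_k(t)` are smooth nonnegative drifts and `corr_repair`
#' shrinks toward the identity until the smallest eigenvalue is at least
#' `1e-6`, then rescales to a correlation matrix. The per-window average of
#' `a_k(t)` is stored as approximate ground truth for the windowing stage.
#'
#' @param states A `cddfip_states` object.
#' @param T_full Number of timepoints (>= 2 * `window_len`).
#' @param window_len Window length in TRs used for the stored ground truth.
#' @param snr Governs amplitude of the state term relative to the identity
#'   floor (`lambda = 1`, state term scaled by `snr/(1+snr)`).
#' @param seed Integer seed.
#' @param amax Peak state amplitude before covariance repair.
#' @return `cddfip_subject_sim` with `observed` a `cddfip_timecourses`
#'   object, plus `true_mixing` (window-averaged amplitudes) and
#'   `true_states`.
#' @export
simulate_subject_timecourses <- function(states, T_full, window_len, snr,
                                         seed, amax = 0.8) {
  stopifnot(inherits(states, "cddfip_states"))
  T_full <- as.integer(T_full); window_len <- as.integer(window_len)
  if (T_full < 2L * window_len) {
    abort("`T_full` must be at least 2 * window_len.",
          class = "cddfip_param_error")
  }
  if (snr <= 0) abort("`snr` must be positive.", class = "cddfip_param_error")
  S <- states$states
  K <- nrow(S); M <- states$n_networks
  set.seed(as.integer(seed) %% .Machine$integer.max)
  gain <- snr / (1 + snr)
  a <- vapply(seq_len(K), function(k) {
    x <- smooth_mixing(T_full, ceiling(T_full / 20))
    amax * gain * abs(x) / max(abs(x), 1)
  }, numeric(T_full))
  basis <- lapply(seq_len(K), function(k) devectorize_upper(S[k, ]))
  X <- matrix(0, T_full, M)
  for (t in seq_len(T_full)) {
    C <- diag(M)
    for (k in seq_len(K)) C <- C + a[t, k] * basis[[k]]
    C <- repair_correlation(C)
    L <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(L)) {
      abort("covariance repair failed: matrix not positive definite.",
            class = "cddfip_generation_error")
    }
    X[t, ] <- as.numeric(rnorm(M) %*% L)
  }
  Wn <- T_full - window_len + 1L
  A_win <- vapply(seq_len(K), function(k) {
    vapply(seq_len(Wn), function(w) mean(a[w:(w + window_len - 1L), k]),
           numeric(1))
  }, numeric(Wn))
  tc <- structure(
    list(values = X, tr_seconds = NA_real_, subject_id = NA_character_),
    class = "cddfip_timecourses"
  )
  structure(
    list(observed = tc, true_mixing = A_win, true_states = S,
         level = "timecourse", seed = as.integer(seed)),
    class = "cddfip_subject_sim"
  )
}

# shrink toward identity until min eigenvalue >= 1e-6, rescale to correlation
repair_correlation <- function(C, min_eig = 1e-6) {
  for (gamma in c(0, 0.1, 0.2, 0.4, 0.6, 0.8, 0.95, 1)) {
    Cs <- (1 - gamma) * C + gamma * diag(nrow(C))
    ev <- min(eigen(Cs, symmetric = TRUE, only.values = TRUE)$values)
    if (ev >= min_eig) {
      d <- sqrt(diag(Cs))
      return(Cs / tcrossprod(d))
    }
  }
  abort("covariance repair failed to reach positive definiteness.",
        class = "cddfip_generation_error")
}

#' Simulate a labeled two-group cohort
#'
#' Draws `n_per_group` control and `n_per_group` patient subjects from the
#' same ground-truth states, with an optional planted group effect applied to
#' the patient group:
#'
#' * `"none"` — groups are exchangeable.
#' * `"amplitude_variance"` — patient mixing amplitudes of `effect_states`
#'   are scaled by `sqrt(1 + magnitude)`, raising their variance by
#'   `magnitude` (e.g. `0.5` for +50%), the planted analogue of greater
#'   dynamic variability.
#' * `"occupancy_bias"` — patient amplitude of `effect_states` scaled by
#'   `1 + magnitude`, biasing dominance toward those states.
#' * `"density_shift"` — all patient amplitudes scaled by `1 + magnitude`,
#'   pushing more states above a fixed strong-state threshold.
#'
#' Covariates (age, sex, site) are independent draws. All randomness derives
#' from `seed` via a deterministic per-subject split.
#'
#' @param n_per_group Subjects per group (>= 1).
#' @param K,M Number of states and networks.
#' @param W Windows per subject.
#' @param snr Signal-to-noise variance ratio.
#' @param perturb_sd Subject state perturbation sd.
#' @param group_effect One of `"none"`, `"amplitude_variance"`,
#'   `"occupancy_bias"`, `"density_shift"`.
#' @param effect_magnitude Effect magnitude (see above).
#' @param effect_states Indices of states carrying the effect.
#' @param seed Root seed.
#' @param level Generate subjects at the windowed-FNC level (`"wfnc"`,
#'   default) or as raw timecourses (`"timecourse"`, which exercises the
#'   windowing stage; planted group effects other than `"none"` are only
#'   available at the windowed-FNC level).
#' @param T_full,window_len Timecourse length and window length in TRs,
#'   used only when `level = "timecourse"`.
#' @return A `cddfip_cohort`: list with `subjects` (list of
#'   `cddfip_subject_sim`), `manifest` (tibble: subject_id, group, age, sex,
#'   site, seed), `states` (the ground truth), and the generation settings.
#' @export
simulate_cohort <- function(n_per_group, K = 5, M = 20, W = 100, snr = 5,
                            perturb_sd = 0.2,
                            group_effect = c("none", "amplitude_variance",
                                             "occupancy_bias", "density_shift"),
                            effect_magnitude = 0.5, effect_states = 1L,
                            seed = 1L, level = c("wfnc", "timecourse"),
                            T_full = 160L, window_len = 22L) {
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 1L) {
    abort("`n_per_group` must be >= 1.", class = "cddfip_param_error")
  }
  group_effect <- match.arg(group_effect)
  level <- match.arg(level)
  if (level == "timecourse" && group_effect != "none") {
    abort("planted group effects require the windowed-FNC level.",
          class = "cddfip_param_error")
  }
  states <- make_states(K, M, seed = split_seed(seed, 0L, 1L))
  n <- 2L * n_per_group
  groups <- rep(c("control", "patient"), each = n_per_group)
  subjects <- vector("list", n)
  set.seed(split_seed(seed, 0L, 2L))
  age <- round(rnorm(n, 35, 10), 1)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  site <- sample(paste0("site", 1:3), n, replace = TRUE)
  sub_seeds <- vapply(seq_len(n), function(i) split_seed(seed, i),
                      numeric(1))
  for (i in seq_len(n)) {
    sim <- if (level == "timecourse") {
      simulate_subject_timecourses(states, T_full = T_full,
                                   window_len = window_len, snr = snr,
                                   seed = sub_seeds[i])
    } else {
      simulate_subject_dfnc(states, W = W, snr = snr,
                            perturb_sd = perturb_sd, seed = sub_seeds[i])
    }
    if (groups[i] == "patient" && group_effect != "none") {
      fac <- switch(group_effect,
        amplitude_variance = sqrt(1 + effect_magnitude),
        occupancy_bias = 1 + effect_magnitude,
        density_shift = 1 + effect_magnitude
      )
      A <- sim$true_mixing
      if (group_effect == "density_shift") {
        A <- A * fac
      } else {
        A[, effect_states] <- A[, effect_states] * fac
      }
      noise <- sim$observed$values - sim$true_mixing %*% sim$true_states
      sim$true_mixing <- A
      sim$observed$values <- A %*% sim$true_states + noise
    }
    sim$subject_id <- sprintf("S%03d", i)
    sim$group <- groups[i]
    subjects[[i]] <- sim
  }
  manifest <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)), group = groups,
    age = age, sex = sex, site = site, seed = as.integer(sub_seeds)
  )
  structure(
    list(subjects = subjects, manifest = manifest, states = states,
         n_per_group = n_per_group, K = K, M = M, W = W, snr = snr,
         perturb_sd = perturb_sd, group_effect = group_effect,
         effect_magnitude = effect_magnitude, effect_states = effect_states,
         level = level, seed = as.integer(seed)),
    class = "cddfip_cohort"
  )
}

#' @export
print.cddfip_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic cohort: %d + %d subjects, K = %d states, M = %d networks, W = %d windows, effect = %s>\n",
    x$n_per_group, x$n_per_group, x$K, x$M, x$W, x$group_effect
  ))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes one TSV per subject (windowed-FNC values or timecourses), a
#' manifest CSV with a `path` column, and the ground-truth states/mixing as
#' TSVs under `dir/ground_truth/`. Every file carries a `# cddfip` provenance
#' comment line with the root seed.
#'
#' @param cohort A `cddfip_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (invisibly), with `path` filled in.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cddfip_cohort"))
  dir.create(file.path(dir, "ground_truth"), recursive = TRUE,
             showWarnings = FALSE)
  header <- sprintf("# cddfip cohort seed=%d", cohort$seed)
  paths <- character(length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    paths[i] <- file.path(dir, paste0(s$subject_id, ".tsv"))
    vals <- if (inherits(s$observed, "cddfip_wfnc")) s$observed$values
            else s$observed$values
    writeLines(header, paths[i])
    utils::write.table(vals, paths[i], sep = "\t", row.names = FALSE,
                       col.names = FALSE, append = TRUE)
  }
  manifest <- dplyr::mutate(cohort$manifest, path = paths)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  utils::write.table(cohort$states$states,
                     file.path(dir, "ground_truth", "states.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  for (i in seq_along(cohort$subjects)) {
    utils::write.table(cohort$subjects[[i]]$true_mixing,
                       file.path(dir, "ground_truth",
                                 paste0(cohort$manifest$subject_id[i],
                                        "_mixing.tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(manifest)
}
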
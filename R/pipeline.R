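# Semi-automatic comparison pipeline: burn-in removal, pairwise-similarity
# grouping of runs (Gelman-Rubin-Brooks + between-run Geweke), exploration
# quality (EQ) scoring, and EQ-conditioned sampling efficiency.

# Per-trace summary statistics at a given suffix length, cached by the
# caller: column means, covariance and per-parameter spectral variances.
suffix_stats <- function(trace, len) {
  n <- nrow(trace)
  a <- trace[(n - len + 1):n, , drop = FALSE]
  list(mean = colMeans(a), cov = stats::cov(a),
       sv = apply(a, 2, spectral_variance), n = len)
}

# Two-chain similarity from cached stats: multivariate GRB below threshold
# AND Holm-corrected between-run Geweke tests all passing.
pair_pass_stats <- function(sa, sb, mpsrf_threshold, alpha) {
  d <- length(sa$mean)
  dm <- sa$mean - sb$mean
  W <- (sa$cov + sb$cov) / 2
  if (any(diag(W) <= 0)) return(FALSE)
  Bn <- 0.5 * tcrossprod(dm) # cov of the two mean vectors
  n <- sa$n
  lam <- tryCatch(max(Re(eigen(solve(W, Bn), only.values = TRUE)$values)),
                  error = function(e) Inf)
  mpsrf <- (n - 1) / n + (3 / 2) * lam
  if (!is.finite(mpsrf) || mpsrf >= mpsrf_threshold) return(FALSE)
  sv <- sa$sv + sb$sv
  if (any(sv <= 0)) return(all(dm == 0))
  z <- dm / sqrt(sv)
  p <- 2 * stats::pnorm(-abs(z))
  all(stats::p.adjust(p, "holm") >= alpha)
}

#' Pairwise similarity of two runs
#'
#' Two runs (burn-in already removed) pass iff both the two-chain
#' multivariate Gelman-Rubin-Brooks diagnostic stays below the threshold
#' and the between-run Geweke mean-comparison test (Holm-corrected across
#' parameters) passes. The two traces are truncated to the shorter one's
#' length (suffixes) before testing.
#'
#' @param runA,runB post-burn-in trace matrices (or `sampler_run` objects,
#'   whose full traces are then used).
#' @param mpsrf_threshold multivariate PSRF pass threshold.
#' @param alpha Geweke test level.
#' @return logical.
#' @export
pairwise_similarity <- function(runA, runB, mpsrf_threshold = 1.1,
                                alpha = 0.05) {
  a <- if (inherits(runA, "sampler_run")) runA$trace else as.matrix(runA)
  b <- if (inherits(runB, "sampler_run")) runB$trace else as.matrix(runB)
  len <- min(nrow(a), nrow(b))
  pair_pass_stats(suffix_stats(a, len), suffix_stats(b, len),
                  mpsrf_threshold, alpha)
}

#' Group runs by pairwise similarity
#'
#' Builds the pairwise-similarity graph over all runs of one benchmark and
#' returns its connected components as groups (a run similar to any member
#' joins the entire group). Groups smaller than `min_fraction` of the total
#' run count are marked neglected and excluded from further analysis.
#'
#' @param traces list of post-burn-in trace matrices.
#' @param min_fraction minimum group size as a fraction of the run count.
#' @param mpsrf_threshold,alpha pairwise-test settings, see
#'   [pairwise_similarity()].
#' @return a list of class `grouping_result`: `partition` (group id per
#'   run), `group_sizes`, `neglected` (per group), `pass_matrix`,
#'   `min_size`.
#' @export
group_runs <- function(traces, min_fraction = 0.05, mpsrf_threshold = 1.1,
                       alpha = 0.05) {
  R <- length(traces)
  stopifnot(R >= 2)
  traces <- lapply(traces, as.matrix)
  lens <- vapply(traces, nrow, 0L)
  cache <- new.env(parent = emptyenv())
  get_stats <- function(i, len) {
    key <- paste0(i, "_", len)
    s <- cache[[key]]
    if (is.null(s)) {
      s <- suffix_stats(traces[[i]], len)
      cache[[key]] <- s
    }
    s
  }
  pass <- matrix(FALSE, R, R)
  diag(pass) <- TRUE
  parent <- seq_len(R)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    len <- min(lens[i], lens[j])
    ok <- len >= 20 &&
      pair_pass_stats(get_stats(i, len), get_stats(j, len),
                      mpsrf_threshold, alpha)
    pass[i, j] <- pass[j, i] <- ok
    if (ok) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(R), find, 0L)
  partition <- as.integer(factor(roots))
  sizes <- tabulate(partition)
  min_size <- ceiling(min_fraction * R)
  structure(list(partition = partition, group_sizes = sizes,
                 neglected = sizes < min_size, pass_matrix = pass,
                 min_size = min_size),
            class = "grouping_result")
}

#' Exploration-quality assessment
#'
#' For every retained (non-neglected) group `G` and every other retained
#' group `G2`, `G` covers `G2` iff (mode criterion) `G`'s best observed
#' log-posterior is within `delta_mode` of `G2`'s best, and (tail
#' criterion) for every parameter `G`'s pooled outer sample interval
#' (1%-99% by default) contains `G2`'s pooled inner interval (5%-95%). A
#' group is well-exploring iff it covers all other retained groups. The EQ
#' of a scenario is the fraction of its runs belonging to well-exploring
#' groups.
#'
#' @param grouping a [group_runs()] result.
#' @param traces list of post-burn-in trace matrices (as used for grouping).
#' @param lp list of post-burn-in log-posterior vectors, one per run.
#' @param scenarios character vector of scenario labels, one per run.
#' @param delta_mode mode-coverage tolerance in log-posterior units.
#' @param q_outer,q_inner quantile pairs for the tail criterion.
#' @return a list of class `eq_result`: `well_exploring` (per group),
#'   `run_well` (per run), `eq` (named per scenario, in `[0, 1]`),
#'   `no_retained` flag.
#' @export
assess_exploration <- function(grouping, traces, lp, scenarios,
                               delta_mode = 5, q_outer = c(0.01, 0.99),
                               q_inner = c(0.05, 0.95)) {
  part <- grouping$partition
  G <- max(part)
  retained <- which(!grouping$neglected)
  scen <- unique(scenarios)
  if (length(retained) == 0) {
    return(structure(list(well_exploring = rep(FALSE, G),
                          run_well = rep(FALSE, length(part)),
                          eq = setNames(rep(0, length(scen)), scen),
                          no_retained = TRUE),
                     class = "eq_result"))
  }
  gstats <- lapply(seq_len(G), function(g) {
    runs <- which(part == g)
    pool <- do.call(rbind, lapply(runs, function(i) as.matrix(traces[[i]])))
    list(best_lp = max(unlist(lp[runs]), na.rm = TRUE),
         outer = apply(pool, 2, stats::quantile, probs = q_outer, names = FALSE),
         inner = apply(pool, 2, stats::quantile, probs = q_inner, names = FALSE))
  })
  # groups that found the high-posterior region: only their samples count
  # as posterior tails that other groups must cover. Groups that never
  # reached high posterior probability must still be beaten on the mode
  # criterion, but their (non-representative) spread is not a coverage
  # obligation for others.
  best_all <- max(vapply(retained, function(g) gstats[[g]]$best_lp, 0))
  relevant <- retained[vapply(retained, function(g)
    gstats[[g]]$best_lp >= best_all - delta_mode, TRUE)]
  covers <- function(g, g2) {
    a <- gstats[[g]]; b <- gstats[[g2]]
    if (a$best_lp < b$best_lp - delta_mode) return(FALSE)
    if (!(g2 %in% relevant)) return(TRUE)
    all(a$outer[1, ] <= b$inner[1, ]) && all(a$outer[2, ] >= b$inner[2, ])
  }
  well <- rep(FALSE, G)
  for (g in retained)
    well[g] <- all(vapply(setdiff(retained, g), covers, TRUE, g = g))
  run_well <- well[part] & !grouping$neglected[part]
  eq <- vapply(scen, function(s) mean(run_well[scenarios == s]), 0)
  structure(list(well_exploring = well, run_well = run_well,
                 eq = eq, no_retained = FALSE),
            class = "eq_result")
}

#' EQ-conditioned sampling efficiency
#'
#' `ESS/s` multiplied by the scenario's exploration quality. An EQ of zero
#' nullifies the efficiency regardless of speed, which penalizes runs that
#' are fast because they never explore.
#'
#' @param ess effective sample size(s).
#' @param cpu_seconds CPU seconds (> 0).
#' @param eq exploration quality in `[0, 1]`.
#' @return `(ess / cpu_seconds) * eq`.
#' @export
conditioned_efficiency <- function(ess, cpu_seconds, eq) {
  if (any(cpu_seconds <= 0)) stop("cpu_seconds must be positive")
  stopifnot(all(eq >= 0 & eq <= 1))
  (ess / cpu_seconds) * eq
}

#' Summarize a study of sampler runs
#'
#' Applies the full analysis pipeline to all runs of one benchmark problem:
#' automatic burn-in removal per run, similarity grouping across all runs,
#' exploration-quality scoring per scenario, and per-scenario effective
#' sample sizes. Runs outside well-exploring groups — and runs flagged
#' non-converged by the burn-in test — contribute an ESS of zero (they do
#' not provide a representative posterior sample). Non-converged runs still
#' participate in grouping, represented by the second half of their trace.
#'
#' @param runs list of [run_sampler()] results for one benchmark.
#' @param alpha test level for burn-in and pairwise Geweke tests.
#' @param mpsrf_threshold pairwise GRB pass threshold.
#' @param min_fraction minimum retained group-size fraction.
#' @param delta_mode,q_outer,q_inner exploration-quality settings, see
#'   [assess_exploration()].
#' @return a tibble of class `study_summary` with one row per scenario:
#'   `scenario`, `n_runs`, `eq`, `median_ess`, `median_ess_per_s`,
#'   `conditioned_ess_per_s`. Attributes `grouping`, `exploration` and
#'   `run_table` (per-run tibble) carry the underlying detail.
#' @export
summarize_study <- function(runs, alpha = 0.05, mpsrf_threshold = 1.1,
                            min_fraction = 0.05, delta_mode = 5,
                            q_outer = c(0.01, 0.99), q_inner = c(0.05, 0.95)) {
  stopifnot(length(runs) >= 2)
  scenarios <- vapply(runs, function(r) r$scenario %||% r$algorithm, "")
  bi <- lapply(runs, function(r)
    tryCatch(estimate_burnin(r$trace, alpha = alpha),
             error = function(e) list(n_bi = nrow(r$trace), converged = FALSE)))
  post <- vector("list", length(runs))
  post_lp <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    n <- nrow(runs[[i]]$trace)
    from <- if (bi[[i]]$converged) bi[[i]]$n_bi + 1 else floor(n / 2) + 1
    post[[i]] <- runs[[i]]$trace[from:n, , drop = FALSE]
    post_lp[[i]] <- runs[[i]]$log_posterior[from:n]
  }
  grouping <- group_runs(post, min_fraction = min_fraction,
                         mpsrf_threshold = mpsrf_threshold, alpha = alpha)
  eq <- assess_exploration(grouping, post, post_lp, scenarios,
                           delta_mode = delta_mode, q_outer = q_outer,
                           q_inner = q_inner)
  ess <- vapply(seq_along(runs), function(i) {
    if (!eq$run_well[i] || !bi[[i]]$converged) return(0)
    if (nrow(post[[i]]) < 100) return(0)
    # a degenerate (constant-parameter) trace has no usable sample
    tryCatch(effective_sample_size(post[[i]])$ess, error = function(e) 0)
  }, 0)
  cpu <- vapply(runs, function(r) r$cpu_seconds, 0)
  run_table <- tibble::tibble(
    run = seq_along(runs), scenario = scenarios,
    n_bi = vapply(bi, function(b) as.numeric(b$n_bi), 0),
    converged = vapply(bi, function(b) b$converged, TRUE),
    group = grouping$partition,
    neglected = grouping$neglected[grouping$partition],
    well_exploring = eq$run_well,
    ess = ess, cpu_seconds = cpu, ess_per_s = ess / cpu)
  out <- run_table |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(n_runs = dplyr::n(),
                     eq = eq$eq[[unique(.data$scenario)]],
                     median_ess = stats::median(.data$ess),
                     median_ess_per_s = stats::median(.data$ess_per_s),
                     .groups = "drop") |>
    dplyr::mutate(conditioned_ess_per_s = .data$eq * .data$median_ess_per_s)
  attr(out, "grouping") <- grouping
  attr(out, "exploration") <- eq
  attr(out, "run_table") <- run_table
  class(out) <- c("study_summary", class(out))
  out
}
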
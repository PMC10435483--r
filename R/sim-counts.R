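#' Simulate a region-level count matrix with known fold changes
#'
#' Direct negative-binomial count generator for calibrating and powering
#' the differential-occupancy test without going through full tracks:
#' per-region means are drawn log-uniformly, treated-condition means are
#' scaled by the supplied fold change, and counts are NB-distributed with
#' a common dispersion (Poisson when `dispersion = 0`).
#'
#' @param n_regions number of regions (rows).
#' @param n_control,n_treated replicates per condition.
#' @param mu_range range of per-region control means (log-uniform draw).
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param fc fold change applied to treated means; scalar or per-region.
#' @param seed integer seed.
#' @return list with `counts` (integer matrix, regions x samples),
#'   `design` (named character vector of conditions) and `mu` (control
#'   means).
#' @export
simulate_count_matrix <- function(n_regions, n_control = 3L, n_treated = 3L,
                                  mu_range = c(20, 200), dispersion = 0.05,
                                  fc = 1, seed = 1L) {
  set.seed(seed)
  mu <- exp(stats::runif(n_regions, log(mu_range[1]), log(mu_range[2])))
  fc <- rep_len(fc, n_regions)
  draw <- function(m) {
    if (dispersion > 0)
      stats::rnbinom(length(m), mu = m, size = 1 / dispersion)
    else stats::rpois(length(m), m)
  }
  ctrl <- vapply(seq_len(n_control), function(i) draw(mu),
                 numeric(n_regions))
  trt <- vapply(seq_len(n_treated), function(i) draw(mu * fc),
                numeric(n_regions))
  counts <- cbind(ctrl, trt)
  colnames(counts) <- c(paste0("control_", seq_len(n_control)),
                        paste0("treated_", seq_len(n_treated)))
  rownames(counts) <- sprintf("r%05d", seq_len(n_regions))
  design <- stats::setNames(rep(c("control", "treated"),
                                c(n_control, n_treated)),
                            colnames(counts))
  list(counts = counts, design = design, mu = mu)
}
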
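## Clade dating by the rho statistic, clock conversion to years, and
## cross-method consensus intervals.

#' The rho statistic with its genealogy-based standard error
#'
#' rho is the mean number of mutations separating each sampled haplotype in
#' a clade from the clade's root haplotype. With edge mutation counts m_j
#' and subtended tip counts n_j (sample multiplicity honored) over the n
#' tips of the clade:
#' rho = (1/n) * sum_j n_j * m_j, and the heuristic Poisson standard error
#' from the genealogy is sigma^2 = (1/n^2) * sum_j n_j^2 * m_j. For a star
#' genealogy this reduces to sigma^2 = rho / n.
#'
#' @param tree an `mp_tree`.
#' @param clade_root node id of the clade root (default the tree root).
#' @param clade_id identifier stored in the result.
#' @return object of class `rho_result` with fields `clade_id`, `n`, `rho`,
#'   `sigma`.
#' @export
rho_sigma <- function(tree, clade_root = tree$root,
                      clade_id = tree$root_label) {
  stopifnot(inherits(tree, "mp_tree"))
  below <- mp_tips_below(tree)
  n <- below[clade_root]
  if (n < 1L) stop("clade has no tips")
  desc <- mp_descendants(tree, clade_root)
  m_j <- vapply(tree$mutations[desc], nrow, 1L)
  n_j <- below[desc]
  rho <- sum(n_j * m_j) / n
  sigma2 <- sum(n_j^2 * m_j) / n^2
  structure(list(clade_id = clade_id, n = as.integer(n), rho = rho,
                 sigma = sqrt(sigma2)),
            class = "rho_result")
}

#' @export
print.rho_result <- function(x, ...) {
  cat("rho = ", signif(x$rho, 4), " +/- ", signif(x$sigma, 4),
      " mutations (n = ", x$n, ", clade ", x$clade_id, ")\n", sep = "")
  invisible(x)
}

#' Independent path-walking mean root-to-tip distance
#'
#' Computes the mean over tips (with multiplicity) of the number of
#' mutations on the root-to-tip path; used as an oracle for [rho_sigma()].
#'
#' @param tree an `mp_tree`.
#' @param clade_root clade root node id.
#' @return numeric mean path length in mutations.
#' @export
mean_root_tip_distance <- function(tree, clade_root = tree$root) {
  tips <- intersect(which(tree$is_tip),
                    c(clade_root, mp_descendants(tree, clade_root)))
  tot <- 0; n <- 0
  for (tp in tips) {
    d <- 0L; v <- tp
    while (v != clade_root) {
      d <- d + nrow(tree$mutations[[v]])
      v <- tree$parent[v]
    }
    k <- length(tree$samples[[tp]])
    tot <- tot + d * k; n <- n + k
  }
  tot / n
}

#' Construct a molecular clock model
#'
#' Converts whole-mitogenome mutational distances to years. The default is
#' the uncorrected linear clock of one substitution per 3,624 years for the
#' entire mitogenome. A purifying-selection correction can be supplied as a
#' two-column table (substitutions, years), strictly increasing in both
#' columns; the correction is applied by monotone linear interpolation (and
#' linear extrapolation beyond the last row), anchored at (0, 0).
#'
#' @param years_per_substitution positive rate, default 3624.
#' @param correction_table optional data.frame with columns `substitutions`
#'   and `years`.
#' @return object of class `clock_model`; its `$correction` element maps a
#'   nonnegative substitution count to years.
#' @export
clock_model <- function(years_per_substitution = 3624,
                        correction_table = NULL) {
  stopifnot(is.numeric(years_per_substitution),
            years_per_substitution > 0)
  if (is.null(correction_table)) {
    correction <- function(subs) subs * years_per_substitution
  } else {
    stopifnot(is.data.frame(correction_table),
              all(c("substitutions", "years") %in% names(correction_table)))
    x <- correction_table$substitutions
    y <- correction_table$years
    if (any(diff(x) <= 0) || any(diff(y) <= 0))
      stop("correction table must be strictly increasing in both columns")
    if (x[1L] > 0) { x <- c(0, x); y <- c(0, y) }
    if (y[1L] != 0 || x[1L] != 0)
      stop("correction must map 0 substitutions to 0 years")
    slope_end <- (y[length(y)] - y[length(y) - 1L]) /
      (x[length(x)] - x[length(x) - 1L])
    correction <- function(subs) {
      out <- stats::approx(x, y, xout = pmin(subs, max(x)), rule = 2)$y
      over <- subs > max(x)
      out[over] <- y[length(y)] + (subs[over] - max(x)) * slope_end
      out
    }
  }
  structure(list(years_per_substitution = years_per_substitution,
                 correction = correction,
                 corrected = !is.null(correction_table)),
            class = "clock_model")
}

#' Read a correction curve from TSV
#' @param path two-column TSV (`substitutions`, `years`), strictly
#'   increasing in both columns.
#' @return a `clock_model` using the curve.
#' @export
read_correction_curve <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  clock_model(correction_table = tab)
}

#' An age estimate with its confidence interval
#' @param clade_id clade identifier.
#' @param method `"rho"` or `"ml"`.
#' @param age_years,ci_low_years,ci_high_years nonnegative years with
#'   `ci_low <= age <= ci_high` (truncated at 0).
#' @param flag optional character note (e.g. non-convergence).
#' @return object of class `age_estimate`.
#' @export
age_estimate <- function(clade_id, method, age_years, ci_low_years,
                         ci_high_years, flag = NA_character_) {
  age_years <- max(age_years, 0)
  ci_low_years <- min(max(ci_low_years, 0), age_years)
  ci_high_years <- max(ci_high_years, age_years)
  structure(list(clade_id = clade_id, method = method,
                 age_years = age_years, ci_low_years = ci_low_years,
                 ci_high_years = ci_high_years, flag = flag),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(x$clade_id, " [", x$method, "]: ", round(x$age_years), " years (95% CI ",
      round(x$ci_low_years), "-", round(x$ci_high_years), ")",
      if (!is.na(x$flag)) paste0(" [", x$flag, "]") else "", "\n", sep = "")
  invisible(x)
}

#' Convert a rho result to an age in years
#'
#' The age is the clock correction applied to rho; the confidence interval
#' applies the correction to `rho +/- z * sigma` (truncated at 0). With the
#' default uncorrected clock, one mutation converts to 3,624 years.
#'
#' @param r a `rho_result`.
#' @param clock a `clock_model`, default the uncorrected 3,624-year clock.
#' @param z normal multiplier, default 1.96 for a 95% CI.
#' @return an `age_estimate` with method `"rho"`.
#' @export
rho_age <- function(r, clock = clock_model(), z = 1.96) {
  stopifnot(inherits(r, "rho_result"), inherits(clock, "clock_model"))
  age_estimate(r$clade_id, "rho",
               clock$correction(r$rho),
               clock$correction(max(r$rho - z * r$sigma, 0)),
               clock$correction(r$rho + z * r$sigma))
}

#' Overlap of confidence intervals across methods
#'
#' Returns the intersection `[max of lows, min of highs]` of the supplied
#' estimates' confidence intervals; when the intervals are disjoint the
#' result is flagged empty. The operation is commutative, associative and
#' idempotent.
#'
#' @param estimates list of `age_estimate` (at least one).
#' @return list with `low`, `high`, `empty` (logical).
#' @export
consensus_interval <- function(estimates) {
  stopifnot(length(estimates) >= 1L)
  lows <- vapply(estimates, function(e) e$ci_low_years, 0)
  highs <- vapply(estimates, function(e) e$ci_high_years, 0)
  low <- max(lows); high <- min(highs)
  if (low > high) list(low = NA_real_, high = NA_real_, empty = TRUE)
  else list(low = low, high = high, empty = FALSE)
}

#' Write an age table
#' @param estimates list of `age_estimate`.
#' @param rhos optional named list of `rho_result` by clade_id supplying
#'   `n`, `rho`, `sigma` columns.
#' @param path output TSV path.
#' @return data.frame, invisibly.
#' @export
write_age_table <- function(estimates, path, rhos = NULL) {
  rows <- lapply(estimates, function(e) {
    r <- if (!is.null(rhos)) rhos[[e$clade_id]] else NULL
    data.frame(clade_id = e$clade_id, method = e$method,
               n = if (!is.null(r)) r$n else NA_integer_,
               rho = if (!is.null(r)) r$rho else NA_real_,
               sigma = if (!is.null(r)) r$sigma else NA_real_,
               age_years = e$age_years, ci_low = e$ci_low_years,
               ci_high = e$ci_high_years, flag = e$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
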
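# Selectivity statistics: IC50 <-> free-energy conversion with error
# propagation, paralogue ddG, and method-vs-method regression with the
# deviation metric D.

#' IC50 record
#'
#' @param ligand,target Identifiers.
#' @param ic50 Half-maximal inhibitory concentration in molar (> 0).
#' @param sigma Standard deviation of IC50 across assays, molar (optional).
#' @param note Provenance note (e.g. "mean of ChEMBL assays").
#' @return A one-row data.frame of class `ic50_record`.
#' @export
ic50_record <- function(ligand, target, ic50, sigma = NA_real_, note = "") {
  if (!is.finite(ic50) || ic50 <= 0) stop("ic50_record: IC50 must be positive (molar)")
  if (!is.na(sigma) && sigma < 0) stop("ic50_record: sigma must be >= 0")
  out <- data.frame(ligand = ligand, target = target, ic50 = ic50,
                    sigma = sigma, note = note, stringsAsFactors = FALSE)
  class(out) <- c("ic50_record", "data.frame")
  out
}

#' Convert an IC50 to a binding free energy
#'
#' `dG = R T ln(IC50 in molar)`; nanomolar inhibitors map to roughly -10
#' to -12 kcal/mol at 300 K. The result is tagged as an experimental
#' affinity.
#'
#' @param rec An [ic50_record()] (or data.frame with `ligand`, `target`,
#'   `ic50`, optionally `sigma` in molar).
#' @param ctx A [thermo_context()].
#' @return A data.frame of class `affinity_record` with columns `ligand`,
#'   `target`, `dG` (kcal/mol), `sigma` (kcal/mol, NA when no IC50 sigma
#'   given), `method` = "EXPERIMENT".
#' @export
ic50_to_dG <- function(rec, ctx) {
  assert_ctx(ctx)
  if (any(rec$ic50 <= 0)) stop("ic50_to_dG: IC50 must be positive")
  RT <- thermal_energy(ctx)
  sig <- if ("sigma" %in% names(rec)) ic50_sigma_to_dG_sigma(rec, ctx) else NA_real_
  affinity_record(rec$ligand, rec$target, RT * log(rec$ic50), sig, "EXPERIMENT")
}

#' Propagate an IC50 standard deviation to the free-energy scale
#'
#' First-order propagation through the logarithm:
#' `sigma_dG = R T sigma_IC50 / IC50`.
#'
#' @inheritParams ic50_to_dG
#' @return Numeric sigma in kcal/mol; `NA` (absent, not zero) when the
#'   record carries no sigma.
#' @export
ic50_sigma_to_dG_sigma <- function(rec, ctx) {
  assert_ctx(ctx)
  if (!"sigma" %in% names(rec)) return(rep(NA_real_, nrow(rec)))
  if (any(!is.na(rec$sigma) & rec$sigma < 0)) stop("ic50_sigma_to_dG_sigma: sigma must be >= 0")
  ifelse(is.na(rec$sigma), NA_real_, thermal_energy(ctx) * rec$sigma / rec$ic50)
}

#' Affinity record
#'
#' @param ligand,target Identifiers.
#' @param dG Binding free energy, kcal/mol (negative = favourable).
#' @param sigma One standard deviation, kcal/mol (NA allowed).
#' @param method One of "MMPBSA", "ABFE", "US", "EXPERIMENT".
#' @return A data.frame of class `affinity_record` (vectorised over rows).
#' @export
affinity_record <- function(ligand, target, dG, sigma = NA_real_, method) {
  if (any(!is.na(sigma) & sigma < 0)) stop("affinity_record: sigma must be >= 0")
  out <- data.frame(ligand = ligand, target = target, dG = dG,
                    sigma = sigma, method = method, stringsAsFactors = FALSE)
  class(out) <- c("affinity_record", "data.frame")
  out
}

#' Paralogue selectivity ddG for one ligand
#'
#' `ddG = dG(target1) - dG(target2)` for the same ligand measured or
#' computed by the same method, with uncertainties combined in
#' quadrature. Negative ddG means the ligand is selective for target1.
#'
#' @param a,b Single-row [affinity_record()]s for the two targets.
#' @return A one-row data.frame: `ligand`, `target1`, `target2`, `ddG`,
#'   `sigma`, `method`.
#' @export
ddG_selectivity <- function(a, b) {
  if (nrow(a) != 1L || nrow(b) != 1L) stop("ddG_selectivity: expects single records")
  if (a$ligand != b$ligand) stop("ddG_selectivity: records are for different ligands")
  if (a$method != b$method) stop("ddG_selectivity: records are from different methods")
  sig <- if (is.na(a$sigma) && is.na(b$sigma)) NA_real_ else
    sqrt(sum(c(a$sigma, b$sigma)^2, na.rm = TRUE))
  data.frame(ligand = a$ligand, target1 = a$target, target2 = b$target,
             ddG = a$dG - b$dG, sigma = sig, method = a$method,
             stringsAsFactors = FALSE)
}

#' Linear regression with the deviation metric D
#'
#' Ordinary least squares of y on x (unweighted; sigmas, when present on
#' the points, are carried for display only), the coefficient of
#' determination R^2, and the deviation metric
#' `D = sqrt( (1/n) sum_i (y_fit,i - y_data,i)^2 )` -- the root mean
#' squared residual about the fitted line, in kcal/mol. Ligands named in
#' `exclude` are dropped before fitting and logged in the report.
#'
#' @param points Data.frame with columns `x`, `y` and optionally `ligand`,
#'   `sigma_x`, `sigma_y`.
#' @param exclude Character vector of ligand ids to leave out.
#' @return A list of class `correlation_report`: `slope`, `intercept`,
#'   `r_squared`, `D`, `n`, `points` (with `y_fit` and `residual`
#'   columns), `excluded`.
#' @export
regression_with_deviation <- function(points, exclude = NULL) {
  points <- as.data.frame(points)
  excluded <- character(0)
  if (!is.null(exclude) && "ligand" %in% names(points)) {
    drop <- points$ligand %in% exclude
    excluded <- unique(points$ligand[drop])
    points <- points[!drop, , drop = FALSE]
  }
  n <- nrow(points)
  if (n < 3L) stop("regression_with_deviation: need >= 3 points after exclusions")
  if (stats::var(points$x) == 0) stop("regression_with_deviation: zero variance in x (degenerate fit)")
  fit <- stats::lm(y ~ x, data = points)
  co <- stats::coef(fit)
  points$y_fit <- as.numeric(stats::fitted(fit))
  points$residual <- points$y - points$y_fit
  D <- sqrt(mean(points$residual^2))
  ss_tot <- sum((points$y - mean(points$y))^2)
  # a perfect fit of constant y is R^2 = 1, not 0/0
  r2 <- if (ss_tot > 0) 1 - sum(points$residual^2) / ss_tot else 1
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r_squared = r2, D = D, n = n, points = points,
                 excluded = excluded),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> n = %d: y = %.3f x + %.3f, R^2 = %.4f, D = %.3f kcal/mol\n",
              x$n, x$slope, x$intercept, x$r_squared, x$D))
  if (length(x$excluded)) cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Cross-method selectivity comparison
#'
#' Builds the per-ligand ddG table for every method present in the
#' affinity records and regresses every method pair against each other
#' (the column method as y, the row method as x), reporting R^2 and D for
#' each. Ligands missing one target for a method are listed, never
#' silently dropped.
#'
#' @param affinities An [affinity_record()] data.frame covering ligands x
#'   targets x methods.
#' @param target1,target2 The two paralogue targets defining the ddG sign
#'   convention (ddG = dG_target1 - dG_target2).
#' @param exclude Ligand ids excluded from the regressions (still shown in
#'   the ddG table).
#' @return A list of class `method_comparison`: `ddG` (wide data.frame,
#'   ligand x method), `reports` (named list "x_vs_y" of
#'   [regression_with_deviation()] outputs), `missing` (ligand/method pairs
#'   without both targets).
#' @export
method_comparison_table <- function(affinities, target1, target2, exclude = NULL) {
  affinities <- as.data.frame(affinities)
  methods <- unique(affinities$method)
  ligands <- unique(affinities$ligand)
  ddG <- data.frame(ligand = ligands, stringsAsFactors = FALSE)
  missing <- list()
  for (m in methods) {
    vals <- sigs <- rep(NA_real_, length(ligands))
    for (i in seq_along(ligands)) {
      a <- affinities[affinities$ligand == ligands[i] & affinities$method == m &
                        affinities$target == target1, , drop = FALSE]
      b <- affinities[affinities$ligand == ligands[i] & affinities$method == m &
                        affinities$target == target2, , drop = FALSE]
      if (nrow(a) == 1L && nrow(b) == 1L) {
        d <- ddG_selectivity(a, b)
        vals[i] <- d$ddG; sigs[i] <- d$sigma
      } else {
        missing[[length(missing) + 1L]] <- data.frame(ligand = ligands[i], method = m)
      }
    }
    ddG[[m]] <- vals
    ddG[[paste0(m, "_sigma")]] <- sigs
  }
  reports <- list()
  if (length(methods) > 1L) {
    for (i in seq_along(methods)) for (j in seq_along(methods)) {
      if (i == j) next
      mx <- methods[i]; my <- methods[j]
      pts <- data.frame(ligand = ddG$ligand, x = ddG[[mx]], y = ddG[[my]])
      pts <- pts[stats::complete.cases(pts[, c("x", "y")]), , drop = FALSE]
      rep_name <- paste0(mx, "_vs_", my)
      reports[[rep_name]] <- tryCatch(
        regression_with_deviation(pts, exclude = exclude),
        error = function(e) structure(list(error = conditionMessage(e)),
                                      class = "correlation_report"))
    }
  }
  structure(list(ddG = ddG,
                 reports = reports,
                 missing = if (length(missing)) do.call(rbind, missing) else NULL,
                 target1 = target1, target2 = target2),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> ddG = dG(%s) - dG(%s), %d ligands\n",
              x$target1, x$target2, nrow(x$ddG)))
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    if (!is.null(r$error)) {
      cat(sprintf("  %-28s %s\n", nm, r$error))
    } else {
      cat(sprintf("  %-28s R^2 = %.4f, D = %.3f kcal/mol (n = %d)\n",
                  nm, r$r_squared, r$D, r$n))
    }
  }
  if (!is.null(x$missing)) cat(sprintf("  %d ligand/method pairs missing a target\n", nrow(x$missing)))
  invisible(x)
}
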
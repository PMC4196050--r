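#' Validation accuracy of genomic predictions
#'
#' \deqn{r_v = r_{\hat g, DRP} / \bar r_{DRP}}
#' the Pearson correlation between predictions and the validation animals'
#' DRP, divided by the average square root of the DRP reliabilities of the
#' same animals.  The denominator corrects the attenuation of the
#' correlation caused by noise in the DRP, so \eqn{r_v} estimates the
#' correlation with true breeding values and can exceed 1 by construction.
#'
#' @param g_hat predicted breeding values (DGV/GEBV) of the validation
#'   animals.
#' @param drp their de-regressed proofs.
#' @param rel_drp their DRP reliabilities.
#' @return scalar validation accuracy.
#' @export
accuracy_rv <- function(g_hat, drp, rel_drp) {
  stopifnot(length(g_hat) == length(drp), length(drp) == length(rel_drp))
  if (length(drp) < 2L) stop("at least two validation animals are required")
  if (stats::sd(g_hat) == 0 || stats::sd(drp) == 0) {
    stop("validation accuracy undefined: zero variance in predictions or DRP")
  }
  stats::cor(g_hat, drp) / mean(sqrt(rel_drp))
}

#' Accuracy report by method and validation subgroup
#'
#' Summarises one or more fits over the validation cows, overall and split
#' by whether a cow's dam is genotyped: subgroup `"all"`, `"genotyped_dam"`
#' and `"nongeno_dam"` (cows whose dams carry DRP but no genotype; in the
#' emulated design these cows also have non-genotyped half-sisters).  For
#' each method x subgroup cell the realized accuracy \eqn{r_v} (with the
#' attenuation denominator averaged over exactly the animals in that cell)
#' and the mean theoretical accuracy are reported.  Rows with fewer than
#' two animals are skipped with a warning.  The report is deterministic
#' given the fits.
#'
#' @param fits named list of `gblup` fits (names become the `method`
#'   column).
#' @param ped the pedigree (cohort labels and dam links are read from it).
#' @param traits trait records carrying the validation cows' `drp` and
#'   `rel_drp`.
#' @return data frame with columns `method`, `subgroup`, `n`, `r_v`,
#'   `mean_theo_acc`.
#' @export
accuracy_report <- function(fits, ped, traits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    stop("fits must be a named list (names identify methods)")
  }
  ped <- as_pedigree(ped)
  val <- ped$animal[ped$cohort == "val_cow"]
  if (length(val) < 2L) stop("fewer than two validation cows in the pedigree")
  ti <- match(val, traits$animal)
  ok <- !is.na(ti) & !is.na(traits$drp[ti]) & !is.na(traits$rel_drp[ti])
  val <- val[ok]; ti <- ti[ok]
  dam <- ped$dam[match(val, ped$animal)]
  dam_geno <- ped$genotyped[match(dam, ped$animal)]
  sub <- ifelse(!is.na(dam_geno) & dam_geno, "genotyped_dam", "nongeno_dam")
  groups <- list(all = seq_along(val),
                 genotyped_dam = which(sub == "genotyped_dam"),
                 nongeno_dam = which(sub == "nongeno_dam"))
  rows <- list()
  for (meth in names(fits)) {
    fit <- fits[[meth]]
    if (!all(val %in% names(fit$g))) {
      stop("fit '", meth, "' does not cover all validation cows")
    }
    for (gname in names(groups)) {
      idx <- groups[[gname]]
      if (length(idx) < 2L) {
        warning("subgroup '", gname, "' has fewer than 2 animals; row skipped")
        next
      }
      v <- val[idx]
      rows[[length(rows) + 1L]] <- data.frame(
        method = meth, subgroup = gname, n = length(idx),
        r_v = accuracy_rv(fit$g[v], traits$drp[ti[idx]], traits$rel_drp[ti[idx]]),
        mean_theo_acc = mean(fit$accuracy[v]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write an accuracy report as TSV
#' @param report data frame from [accuracy_report()] or [run_scenario()].
#' @param file output path.
#' @export
write_report <- function(report, file) {
  utils::write.table(report, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
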
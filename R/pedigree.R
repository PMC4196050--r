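#' Validate and normalise a pedigree table
#'
#' A pedigree is a data frame with one row per animal carrying at least the
#' columns `animal`, `sire` and `dam` (character IDs; `"0"` or `NA` marks an
#' unknown parent).  Optional columns used elsewhere in the package are
#' `order` (birth order), `genotyped` (logical), `cohort` and `sex`.
#' Rows must be topologically ordered: every known parent appears in an
#' earlier row than its offspring, which also rules out pedigree loops
#' (no animal can be its own ancestor).
#'
#' @param ped data frame with columns `animal`, `sire`, `dam`.
#' @return the pedigree with IDs coerced to character, unknown parents
#'   encoded as `NA`, and an integer row index usable for matrix building.
#' @export
as_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped), all(c("animal", "sire", "dam") %in% names(ped)))
  ped$animal <- as.character(ped$animal)
  ped$sire <- .norm_parent(ped$sire)
  ped$dam <- .norm_parent(ped$dam)
  if (anyDuplicated(ped$animal)) {
    stop("duplicated animal IDs in pedigree: ",
         paste(unique(ped$animal[duplicated(ped$animal)]), collapse = ", "))
  }
  idx <- match(ped$animal, ped$animal)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  if (any(!is.na(ped$sire) & is.na(si)) || any(!is.na(ped$dam) & is.na(di))) {
    stop("pedigree refers to parents that have no own row; ",
         "add them as founders or encode them as unknown (0/NA)")
  }
  bad <- which(!is.na(si) & si >= idx | !is.na(di) & di >= idx)
  if (length(bad)) {
    stop("pedigree is not topologically ordered (parents must precede ",
         "offspring); first offending animal: ", ped$animal[bad[1]])
  }
  attr(ped, "sire_idx") <- si
  attr(ped, "dam_idx") <- di
  class(ped) <- c("pedigree", "data.frame")
  ped
}

.norm_parent <- function(x) {
  x <- as.character(x)
  x[x %in% c("0", "", "NA") | is.na(x)] <- NA_character_
  x
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree with", nrow(x), "animals")
  if ("genotyped" %in% names(x)) {
    cat(" (", sum(x$genotyped), " genotyped)", sep = "")
  }
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Write a pedigree to CSV
#'
#' Unknown parents are written as `0`.  Columns beyond the standard seven
#' (`animal,sire,dam,order,genotyped,cohort,sex`) are dropped.
#'
#' @param ped pedigree (see [as_pedigree()]).
#' @param file path to write to.
#' @export
write_pedigree <- function(ped, file) {
  out <- as.data.frame(ped)
  for (col in c("order", "genotyped", "cohort", "sex")) {
    if (!col %in% names(out)) out[[col]] <- NA
  }
  out <- out[c("animal", "sire", "dam", "order", "genotyped", "cohort", "sex")]
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a pedigree written by [write_pedigree()]
#' @param file CSV path.
#' @return a validated pedigree.
#' @export
read_pedigree <- function(file) {
  as_pedigree(utils::read.csv(file, stringsAsFactors = FALSE))
}
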
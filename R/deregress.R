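#' De-regress estimated breeding values
#'
#' Converts EBV into de-regressed proofs (DRP) usable as pseudo-phenotypes:
#' the parent-average (PA) contribution and the shrinkage of the genetic
#' evaluation are removed so that, in expectation, the regression of DRP on
#' true breeding value has slope 1 (raw EBV regress with slope equal to
#' their reliability).
#'
#' For an animal with EBV reliability \eqn{r^2}, parent average
#' \eqn{PA = (ebv_{sire} + ebv_{dam})/2} (a missing parent contributes 0
#' with reliability 0) and PA reliability
#' \eqn{r^2_{PA} = (r^2_{sire} + r^2_{dam})/4}, the own-performance
#' reliability is \eqn{r^2_{own} = (r^2 - r^2_{PA}) / (1 - r^2_{PA})} and
#' \deqn{DRP = PA + (ebv - PA) / r^2_{own},}
#' with `rel_drp` set to \eqn{r^2_{own}}.  Animals whose EBV reliability
#' does not exceed their PA reliability carry no own information; they are
#' flagged `excluded` (with `NA` DRP) rather than raising an error.
#'
#' @param records data frame with columns `animal`, `ebv`, `rel_ebv`
#'   (reliabilities strictly inside (0, 1)).  Parent EBV and reliabilities
#'   are looked up in this same table via the pedigree; parents without a
#'   record contribute like missing parents.
#' @param ped pedigree (see [as_pedigree()]) supplying sire/dam links.
#' @param min_rel_own smallest own-performance reliability treated as
#'   usable; records at or below it are excluded.
#' @return data frame with columns `animal`, `drp`, `rel_drp`, `excluded`.
#' @export
deregress <- function(records, ped, min_rel_own = 1e-6) {
  stopifnot(is.data.frame(records),
            all(c("animal", "ebv", "rel_ebv") %in% names(records)))
  if (any(records$rel_ebv <= 0 | records$rel_ebv >= 1)) {
    stop("rel_ebv must lie strictly inside (0, 1)")
  }
  ped <- as_pedigree(ped)
  i <- match(records$animal, ped$animal)
  if (anyNA(i)) stop("records contain animals absent from the pedigree")
  look <- function(parent_ids) {
    j <- match(parent_ids, records$animal)
    list(ebv = ifelse(is.na(j), 0, records$ebv[j]),
         rel = ifelse(is.na(j), 0, records$rel_ebv[j]))
  }
  s <- look(ped$sire[i])
  d <- look(ped$dam[i])
  pa <- (s$ebv + d$ebv) / 2
  rel_pa <- (s$rel + d$rel) / 4
  rel_own <- (records$rel_ebv - rel_pa) / (1 - rel_pa)
  excluded <- rel_own <= min_rel_own
  drp <- ifelse(excluded, NA_real_, pa + (records$ebv - pa) / pmax(rel_own, min_rel_own))
  data.frame(animal = records$animal, drp = drp,
             rel_drp = ifelse(excluded, NA_real_, rel_own),
             excluded = excluded, stringsAsFactors = FALSE)
}

#' Apply cohort reliability floors to DRP
#'
#' Marks records as excluded when their DRP reliability does not exceed the
#' floor for their cohort: retention requires `rel_drp` strictly greater
#' than the floor (0.40 for cows, 0.80 for progeny-tested bulls by
#' default).  The filter is idempotent and never un-excludes a record.
#'
#' @param records data frame with columns `cohort`, `rel_drp` and optionally
#'   `excluded`.
#' @param floors named numeric vector with elements `cow` and `bull`.
#' @param verbose print retained/excluded counts.
#' @return `records` with a logical `included` column (and `excluded`
#'   updated).
#' @export
apply_reliability_filters <- function(records,
                                      floors = c(cow = 0.40, bull = 0.80),
                                      verbose = FALSE) {
  stopifnot(is.data.frame(records), all(c("cohort", "rel_drp") %in% names(records)))
  if (!all(c("cow", "bull") %in% names(floors))) {
    stop("floors must carry named elements 'cow' and 'bull'")
  }
  known <- c("founder_sire", "founder_dam", "ref_cow", "ref_bull",
             "val_cow", "nongeno_dam", "nongeno_halfsib")
  if (length(bad <- setdiff(unique(records$cohort), known))) {
    stop("unknown cohort label(s): ", paste(bad, collapse = ", "))
  }
  floor_i <- ifelse(records$cohort %in% c("ref_bull", "founder_sire"),
                    floors[["bull"]], floors[["cow"]])
  prev_excluded <- if ("excluded" %in% names(records)) records$excluded else FALSE
  pass <- !is.na(records$rel_drp) & records$rel_drp > floor_i & !prev_excluded
  records$excluded <- !pass
  records$included <- pass
  if (verbose) {
    message(sum(pass), " records retained, ", sum(!pass),
            " excluded by reliability floors")
  }
  records
}
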
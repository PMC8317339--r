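#' @import data.table
#' @importFrom stats p.adjust pt qt rbinom rpois runif setNames var sd
#' @importFrom utils head tail write.table read.table
NULL

BASES <- c("A", "C", "G", "T")
BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' The 12 directional substitution classes
#'
#' Every single-base substitution is labelled `"<ref>><alt>"` with
#' `ref != alt`, giving 4 x 3 = 12 directional classes (e.g. `"C>T"`).
#' Because sequencing does not preserve which strand a lesion occurred on,
#' each directional class has a reverse-complement partner observed as the
#' same event on the opposite strand; [collapse_class()] maps both partners
#' to one of 6 strand-collapsed classes written pyrimidine-first
#' (e.g. `"C:G>T:A"` for `C>T` / `G>A`).
#'
#' @format Character vector of length 12, ordered by reference base then
#'   alternate base.
#' @export
SUBSTITUTION_CLASSES <- {
  cls <- as.vector(t(outer(BASES, BASES, function(r, a) paste0(r, ">", a))))
  cls[substr(cls, 1, 1) != substr(cls, 3, 3)]
}

#' The 6 strand-collapsed substitution classes
#'
#' Pyrimidine-first labels pairing each directional class with its
#' reverse complement: `C>T` and `G>A` are both reported as `C:G>T:A`.
#'
#' @format Character vector of length 6.
#' @export
COLLAPSED_CLASSES <- c(
  "C:G>A:T", "C:G>G:C", "C:G>T:A",
  "T:A>A:T", "T:A>C:G", "T:A>G:C"
)

#' Build a substitution class label
#'
#' @param ref_base,alt_base Single upper-case bases among A/C/G/T;
#'   vectors are recycled to common length.
#' @return Character vector of directional class labels, e.g. `"C>T"`.
#' @export
#' @examples
#' sub_class("C", "T")
sub_class <- function(ref_base, alt_base) {
  if (!all(ref_base %in% BASES) || !all(alt_base %in% BASES))
    stop("ref_base and alt_base must be one of A, C, G, T")
  if (any(ref_base == alt_base))
    stop("alt_base must differ from ref_base")
  paste0(ref_base, ">", alt_base)
}

class_ref <- function(cls) substr(cls, 1, 1)
class_alt <- function(cls) substr(cls, 3, 3)

#' Reverse-complement a directional substitution class
#'
#' @param cls Character vector of directional class labels.
#' @return The partner class observed on the opposite strand
#'   (`"C>T"` -> `"G>A"`).
#' @export
reverse_complement_class <- function(cls) {
  check_class(cls)
  paste0(BASE_COMPLEMENT[class_ref(cls)], ">", BASE_COMPLEMENT[class_alt(cls)])
}

check_class <- function(cls) {
  bad <- !(cls %in% SUBSTITUTION_CLASSES)
  if (any(bad))
    stop("not a valid substitution class: ", paste(unique(cls[bad]), collapse = ", "))
  invisible(cls)
}

#' Collapse a directional class onto its strand-collapsed identifier
#'
#' Each of the 12 directional classes maps, together with its
#' reverse-complement partner, onto one of 6 collapsed classes written with
#' the pyrimidine-carrying strand first: `C>T` and `G>A` both become
#' `C:G>T:A`; `A>C` and `T>G` both become `T:A>G:C`.
#'
#' @param cls Character vector of directional class labels.
#' @return Character vector of collapsed class labels.
#' @export
#' @examples
#' collapse_class(c("C>T", "G>A", "A>C"))
collapse_class <- function(cls) {
  check_class(cls)
  ref <- class_ref(cls)
  alt <- class_alt(cls)
  # orient so the pyrimidine (C or T) is the reference of the written pair
  flip <- ref %in% c("A", "G")
  ref2 <- ifelse(flip, BASE_COMPLEMENT[ref], ref)
  alt2 <- ifelse(flip, BASE_COMPLEMENT[alt], alt)
  paste0(ref2, ":", BASE_COMPLEMENT[ref2], ">", alt2, ":", BASE_COMPLEMENT[alt2])
}

#' Directional members of a collapsed class
#'
#' @param collapsed A collapsed class label, e.g. `"C:G>T:A"`.
#' @return Character vector of the two directional classes it contains.
#' @export
collapsed_members <- function(collapsed) {
  if (!all(collapsed %in% COLLAPSED_CLASSES))
    stop("not a valid collapsed class: ", collapsed)
  SUBSTITUTION_CLASSES[collapse_class(SUBSTITUTION_CLASSES) %in% collapsed]
}
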
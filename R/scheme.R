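#' Subtype labelling scheme
#'
#' Describes how raw subtype annotations are harmonized before training:
#' which categories exist, which raw labels are merged into broader
#' categories, which raw labels are excluded outright, and how the
#' harmonized categories roll up into higher-level subtype groups for
#' group-wise evaluation.
#'
#' @param labels character vector of harmonized category names.
#' @param merge_map named character vector mapping raw labels to harmonized
#'   labels; every target must be a member of `labels`.
#' @param exclusions character vector of raw labels dropped from the cohort;
#'   disjoint from `labels`.
#' @param group_map named character vector mapping each harmonized label to
#'   a subtype group.
#' @return a `subtype_scheme` object.
#' @seealso [ball_scheme()] for the default B-ALL scheme,
#'   [harmonize_labels()] to apply a scheme.
#' @export
subtype_scheme <- function(labels, merge_map = character(),
                           exclusions = character(), group_map = character()) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate labels", call. = FALSE)
  if (length(merge_map) && !all(merge_map %in% labels))
    stop("merge_map targets must be scheme labels", call. = FALSE)
  if (length(intersect(exclusions, labels)))
    stop("exclusions must be disjoint from labels", call. = FALSE)
  if (length(group_map)) {
    if (!all(labels %in% names(group_map)))
      stop("group_map must cover every label", call. = FALSE)
    if (anyDuplicated(names(group_map)))
      stop("a label may belong to exactly one group", call. = FALSE)
  }
  structure(list(labels = labels, merge_map = merge_map,
                 exclusions = as.character(exclusions),
                 group_map = group_map),
            class = "subtype_scheme")
}

#' @export
print.subtype_scheme <- function(x, ...) {
  cat(sprintf("subtype_scheme: %d categories, %d merge rules, %d exclusions\n",
              length(x$labels), length(x$merge_map), length(x$exclusions)))
  if (length(x$group_map))
    for (g in unique(x$group_map))
      cat(sprintf("  %s: %s\n", g,
                  paste(names(x$group_map)[x$group_map == g], collapse = ", ")))
  invisible(x)
}

#' Default B-ALL subtype scheme
#'
#' The 20 harmonized B-cell acute lymphoblastic leukemia categories used
#' throughout the package, with the two standard merge rules
#' ("ZNF384-like" into the "ZNF384 Group", "KMT2A-like" into the "KMT2A
#' Group"), the exclusion of the small "CRLF2(non-Ph-like)" category, and
#' the four evaluation groups: Fusion Gene, TF Alteration, Ploidy, and Rare
#' Subtype.
#'
#' @return a [subtype_scheme()].
#' @export
ball_scheme <- function() {
  fusion <- c("Ph-like", "Ph", "ETV6-RUNX1", "ETV6-RUNX1-like", "KMT2A Group",
              "TCF3-PBX1", "DUX4", "ZNF384 Group", "MEF2D")
  tf     <- c("PAX5alt", "PAX5 P80R", "IKZF1 N159Y")
  ploidy <- c("High hyperdiploid", "Low hypodiploid", "Low hyperdiploid",
              "Near haploid", "iAMP21")
  rare   <- c("BCL2/MYC", "NUTM1", "HLF")
  labels <- c(fusion, tf, ploidy, rare)
  group_map <- stats::setNames(
    rep(c("Fusion Gene", "TF Alteration", "Ploidy", "Rare Subtype"),
        c(length(fusion), length(tf), length(ploidy), length(rare))),
    labels)
  subtype_scheme(
    labels = labels,
    merge_map = c("ZNF384" = "ZNF384 Group", "ZNF384-like" = "ZNF384 Group",
                  "KMT2A" = "KMT2A Group", "KMT2A-like" = "KMT2A Group"),
    exclusions = "CRLF2(non-Ph-like)",
    group_map = group_map)
}

#' Harmonize raw subtype labels
#'
#' Applies a scheme's merge rules, drops excluded raw labels, samples
#' annotated as "other", and samples carrying two subtype calls (raw labels
#' containing `";"` or `","`). Every kept label is a scheme category;
#' `|kept| + |dropped|` equals the input size.
#'
#' @param raw_labels character vector of raw subtype annotations, named by
#'   sample id (names optional).
#' @param scheme a [subtype_scheme()]; default [ball_scheme()].
#' @return list with `labels` (named character vector of kept assignments)
#'   and `dropped` (data frame of sample, raw label, and drop reason).
#' @export
harmonize_labels <- function(raw_labels, scheme = ball_scheme()) {
  stopifnot(inherits(scheme, "subtype_scheme"))
  raw <- as.character(raw_labels)
  ids <- names(raw_labels) %||% as.character(seq_along(raw))
  dual  <- grepl("[;,]", raw)
  other <- tolower(trimws(raw)) %in% c("other", "others", "unknown")
  excl  <- raw %in% scheme$exclusions
  mapped <- ifelse(raw %in% names(scheme$merge_map),
                   unname(scheme$merge_map[raw]), raw)
  known <- mapped %in% scheme$labels
  bad <- !known & !dual & !other & !excl
  if (any(bad))
    stop("raw label(s) not covered by the scheme: ",
         paste(utils::head(unique(raw[bad]), 3L), collapse = ", "),
         call. = FALSE)
  drop <- dual | other | excl
  reason <- rep(NA_character_, length(raw))
  reason[excl]  <- "excluded subtype"
  reason[other] <- "annotated as other"
  reason[dual]  <- "two subtype calls"
  list(labels = stats::setNames(mapped[!drop], ids[!drop]),
       dropped = data.frame(sample = ids[drop], raw_label = raw[drop],
                            reason = reason[drop], row.names = NULL))
}
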
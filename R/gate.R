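#' Microglia/macrophage phenotype gate
#'
#' An ordered rule table mapping boolean marker vectors to phenotype
#' labels. A rule matches when all its `require` markers are TRUE and all
#' its `forbid` markers are FALSE; the first matching rule wins, and the
#' `default` label covers everything else, so every possible marker vector
#' receives exactly one label.
#'
#' @param rules list of rules, each `list(require =, forbid =, label =)`.
#' @param default label assigned when no rule matches.
#' @param markers marker names a vector must cover to be classifiable.
#' @return An object of class `phenotype_gate`.
#' @export
phenotype_gate <- function(rules, default, markers) {
  stopifnot(is.list(rules), length(rules) >= 1)
  for (r in rules)
    stopifnot(is.character(r$label),
              all(c(r$require, r$forbid) %in% markers))
  structure(list(rules = rules, default = default, markers = markers),
            class = "phenotype_gate")
}

#' @rdname phenotype_gate
#' @details
#' `default_phenotype_gate()` encodes the five-phenotype panel gate for
#' IBA1-seeded microglia/macrophage objects:
#' \enumerate{
#'   \item IBA1 negative: `non_microglia` (QC label);
#'   \item GFAP positive: `gfap_conflict` (QC label — GFAP is carried as an
#'     astrocyte control marker, so an IBA1+GFAP+ call flags a
#'     segmentation or bleed-through conflict and is excluded from the
#'     five phenotypes);
#'   \item P2Y12 positive: `IBA1+P2Y12+` (homeostatic; TMEM119 is
#'     collapsed into this class because nearly all TMEM119+ cells are
#'     also P2Y12+ while the converse fails, so TMEM119 adds no unique
#'     population);
#'   \item ferritin and CD68: `IBA1+Ferritin+CD68+`;
#'   \item ferritin only: `IBA1+Ferritin+`;
#'   \item CD68 only: `IBA1+CD68+`;
#'   \item otherwise `IBA1-only`.
#' }
#' CD45 is recorded per object but takes no part in the gate: its low/high
#' split does not isolate a unique population.
#' @export
default_phenotype_gate <- function() {
  phenotype_gate(
    rules = list(
      list(require = character(), forbid = "IBA1", label = "non_microglia"),
      list(require = "GFAP", forbid = character(), label = "gfap_conflict"),
      list(require = "P2Y12", forbid = character(), label = "IBA1+P2Y12+"),
      list(require = c("Ferritin", "CD68"), forbid = character(),
           label = "IBA1+Ferritin+CD68+"),
      list(require = "Ferritin", forbid = character(), label = "IBA1+Ferritin+"),
      list(require = "CD68", forbid = character(), label = "IBA1+CD68+")),
    default = "IBA1-only",
    markers = c("IBA1", "P2Y12", "TMEM119", "CD45", "CD68", "Ferritin", "GFAP"))
}

#' @rdname phenotype_gate
#' @return `phenotype_labels()`: the five non-QC phenotype labels, in
#'   panel order; `qc_labels()`: the QC labels.
#' @export
phenotype_labels <- function() {
  c("IBA1+P2Y12+", "IBA1-only", "IBA1+Ferritin+", "IBA1+Ferritin+CD68+",
    "IBA1+CD68+")
}

#' @rdname phenotype_gate
#' @export
qc_labels <- function() c("gfap_conflict", "non_microglia")

#' @export
print.phenotype_gate <- function(x, ...) {
  cat(sprintf("<phenotype_gate> %d rules + default '%s' over {%s}\n",
              length(x$rules), x$default, paste(x$markers, collapse = ", ")))
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    cat(sprintf("  %d. %s%s-> %s\n", i,
                if (length(r$require)) paste0(paste(r$require, collapse = "&"), "+ ") else "",
                if (length(r$forbid)) paste0(paste(r$forbid, collapse = "&"), "- ") else "",
                r$label))
  }
  invisible(x)
}

#' Classify marker vectors into phenotypes
#'
#' Applies a [phenotype_gate()] to one or many boolean marker vectors.
#' Evaluation order is deterministic (first matching rule), so every
#' vector maps to exactly one label.
#'
#' @param markers a named logical vector covering the gate's markers, or a
#'   data frame / object table with logical `pos_<marker>` (or bare
#'   marker-name) columns.
#' @param gate a [phenotype_gate()]; default [default_phenotype_gate()].
#' @return Character vector of labels (one per row/vector).
#' @examples
#' classify_phenotype(c(IBA1 = TRUE, P2Y12 = TRUE, TMEM119 = FALSE,
#'                      CD45 = FALSE, CD68 = FALSE, Ferritin = FALSE,
#'                      GFAP = FALSE))
#' @export
classify_phenotype <- function(markers, gate = default_phenotype_gate()) {
  if (is.logical(markers) && !is.null(names(markers)))
    markers <- as.data.frame(as.list(markers))
  if (inherits(markers, "object_set")) markers <- markers$table
  stopifnot(is.data.frame(markers))
  cols <- vapply(gate$markers, function(m) {
    if (paste0("pos_", m) %in% names(markers)) paste0("pos_", m)
    else if (m %in% names(markers)) m
    else NA_character_
  }, character(1))
  if (any(is.na(cols)))
    stop("marker vector is missing gate markers: ",
         paste(gate$markers[is.na(cols)], collapse = ", "), call. = FALSE)
  mm <- as.matrix(markers[, cols, drop = FALSE])
  storage.mode(mm) <- "logical"
  colnames(mm) <- gate$markers
  if (any(is.na(mm))) stop("marker calls must be TRUE/FALSE, not NA", call. = FALSE)
  n <- nrow(mm)
  out <- rep(gate$default, n)
  unassigned <- rep(TRUE, n)
  for (r in gate$rules) {
    hit <- unassigned
    for (m in r$require) hit <- hit & mm[, m]
    for (m in r$forbid) hit <- hit & !mm[, m]
    out[hit] <- r$label
    unassigned <- unassigned & !hit
  }
  out
}

#' Tabulate phenotype labels
#'
#' Exhaustive, disjoint counts over the five phenotype labels plus QC
#' labels; the counts always sum to the number of objects.
#'
#' @param labels character vector of labels, or a classified object
#'   table/`object_set` with a `label` column.
#' @param gate the gate defining the label universe.
#' @return Named integer vector over all gate labels (zero-filled).
#' @export
count_phenotypes <- function(labels, gate = default_phenotype_gate()) {
  if (inherits(labels, "object_set")) labels <- labels$table
  if (is.data.frame(labels)) labels <- labels$label
  universe <- unique(c(vapply(gate$rules, `[[`, character(1), "label"),
                       gate$default))
  extra <- setdiff(unique(labels), universe)
  if (length(extra))
    stop("labels outside the gate's universe: ", paste(extra, collapse = ", "),
         call. = FALSE)
  tab <- table(factor(labels, levels = universe))
  setNames(as.integer(tab), universe)
}
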
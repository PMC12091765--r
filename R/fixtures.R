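# Shipped fixtures: for each of the eight drugs, the edge partition by
# neighborhood eccentricity together with its declared vertex/edge counts,
# and - where the skeleton could be reconstructed and verified against the
# partition - the molecular graph itself. Remdesivir ships partition-level
# only: its printed graph has 41 heavy atoms while the standard structure
# (C27H35N6O8P) has 42, so no reconstruction can be certified.

DRUG_NAMES <- c("arbidol", "chloroquine", "hydroxychloroquine", "lopinavir",
                "remdesivir", "ritonavir", "thalidomide", "theaflavin")

.canon_drug <- function(name) {
  key <- gsub("[^a-z]", "", tolower(name))
  hit <- match(key, gsub("[^a-z]", "", DRUG_NAMES))
  if (is.na(hit)) stop("unknown drug: ", name, call. = FALSE)
  DRUG_NAMES[hit]
}

.extdata <- function(...) {
  system.file("extdata", ..., package = "necindex", mustWork = TRUE)
}

#' Drug fixtures
#'
#' Returns the eight drug fixtures. Each element carries the drug
#' \code{name}, its printed \code{partition} (an \code{edge_partition}), the
#' declared vertex and edge counts, and, for the drugs whose heavy-atom
#' skeleton has been reconstructed and verified to reproduce the printed
#' partition (arbidol, chloroquine, hydroxy-chloroquine, thalidomide), the
#' \code{graph} itself (\code{NULL} otherwise).
#'
#' @return A named list of \code{drug_fixture} objects.
#' @export
drug_fixtures <- function() {
  meta <- utils::read.table(.extdata("partitions", "declared_counts.tsv"),
                            header = TRUE, sep = "\t")
  out <- lapply(DRUG_NAMES, function(nm) {
    row <- meta[meta$drug == nm, ]
    gpath <- system.file("extdata", "graphs", paste0(nm, ".edges"),
                         package = "necindex")
    fx <- list(
      name = nm,
      partition = read_partition_tsv(.extdata("partitions", paste0(nm, ".tsv"))),
      declared_V = row$V,
      declared_E = row$E,
      graph = if (nzchar(gpath)) read_edge_list(gpath) else NULL)
    stopifnot(partition_size(fx$partition) == fx$declared_E)
    if (!is.null(fx$graph)) {
      stopifnot(n_vertices(fx$graph) == fx$declared_V,
                n_edges(fx$graph) == fx$declared_E)
    }
    structure(fx, class = "drug_fixture")
  })
  stats::setNames(out, DRUG_NAMES)
}

#' @export
print.drug_fixture <- function(x, ...) {
  cat(sprintf("<drug_fixture> %s: |V|=%d |E|=%d, %d partition classes%s\n",
              x$name, x$declared_V, x$declared_E, nrow(x$partition),
              if (is.null(x$graph)) " (partition-level only)" else ""))
  invisible(x)
}

#' Physico-chemical property table
#'
#' The eight drugs' boiling point (BP), enthalpy of vaporisation (E, kJ/mol),
#' flash point (FP, deg C), molar refraction (MR, cm^3), polar surface area
#' (PSA, A^2), polarizability (P, cm^3), molar volume (MV, cm^3) and
#' molecular weight (MW, g/mol). Remdesivir's BP, E and FP are not tabulated
#' and are \code{NA}.
#'
#' @param path optional CSV path with a header matching the default column
#'   names; empty cells are missing values. Defaults to the shipped table.
#' @return A data frame with row names the drug identifiers.
#' @export
drug_properties <- function(path = .extdata("properties.csv")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "BP", "E", "FP", "MR", "PSA", "P", "MV", "MW")
  if (!all(need %in% names(df))) {
    stop("property table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rownames(df) <- vapply(df$drug, .canon_drug, character(1))
  df[, setdiff(need, "drug")]
}
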
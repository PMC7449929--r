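#' Construct a SignatureCollection
#'
#' @param sets Named list of character vectors of gene identifiers.
#' @param immune Logical vector (recycled if length 1) flagging the sets whose
#'   scores are summed into the ImmuneScore, or a character vector of set
#'   names to flag.
#'
#' @return A [SignatureCollection-class].
#' @examples
#' sigs <- SignatureCollection(
#'   list(Tcell = c("CD3D", "CD3E"), Glycolysis = c("HK2", "LDHA")),
#'   immune = "Tcell")
#' immuneSignatures(sigs)
#' @export
SignatureCollection <- function(sets, immune = FALSE) {
  if (is.character(immune)) {
    missing <- setdiff(immune, names(sets))
    if (length(missing))
      .stopf("invalidParameter", "unknown immune set(s): %s",
             paste(missing, collapse = ", "))
    immune <- names(sets) %in% immune
  }
  if (length(immune) == 1L) immune <- rep(immune, length(sets))
  new("SignatureCollection", sets = sets, immune = immune)
}

# Immune cell types whose enrichment scores are summed into the ImmuneScore:
# B-cells, CD4+/CD8+ T-cells, dendritic cells, eosinophils, macrophages,
# monocytes, mast cells, neutrophils and NK cells.
.IMMUNE_TYPES <- c("B-cells", "CD4+ T-cells", "CD8+ T-cells",
                   "Dendritic cells", "Eosinophils", "Macrophages",
                   "Monocytes", "Mast cells", "Neutrophils", "NK cells")
.IMMUNE_PREFIX <- c("Bcell", "CD4T", "CD8T", "DC", "Eos", "Macro",
                    "Mono", "Mast", "Neutro", "NK")

#' Default signature collection used by the synthetic cohorts
#'
#' Builds the ten immune cell-type signatures (B-cells, CD4+ and CD8+
#' T-cells, dendritic cells, eosinophils, macrophages, monocytes, mast
#' cells, neutrophils, NK cells) plus a glycolysis signature, with gene
#' identifiers matching those emitted by [generateBulkCohort()]. All sets
#' are disjoint by construction. Real-data analyses should substitute their
#' own collection (e.g. loaded with [readGMT()]); the glycolysis set name is
#' a configurable placeholder, not a curated pathway.
#'
#' @param signatureSize Genes per signature (default 8).
#' @return A [SignatureCollection-class] with 11 sets, 10 flagged immune.
#' @examples
#' defaultSignatureCollection()
#' @export
defaultSignatureCollection <- function(signatureSize = 8L) {
  signatureSize <- .assertCount(signatureSize, "signatureSize")
  sets <- lapply(.IMMUNE_PREFIX, function(p)
    paste0(p, ".g", seq_len(signatureSize)))
  names(sets) <- .IMMUNE_TYPES
  sets$Glycolysis <- paste0("GLYC.g", seq_len(signatureSize))
  SignatureCollection(sets, immune = .IMMUNE_TYPES)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard tab-separated GMT: one set per line, fields are name,
#' description, then gene identifiers. Sets whose description field equals
#' \code{"immune"} are flagged as ImmuneScore summands.
#'
#' @param path Path to a GMT file.
#' @return A [SignatureCollection-class].
#' @seealso [writeGMT()]
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad))
    .stopf("malformedFile", "GMT line(s) with fewer than 3 fields: %s",
           paste(which(bad), collapse = ", "))
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  immune <- vapply(fields, `[[`, "", 2L) == "immune"
  SignatureCollection(sets, immune = immune)
}

#' Write a SignatureCollection to a GMT file
#'
#' The description field carries the immune-summand flag (\code{"immune"} or
#' \code{"other"}) so a round trip through [readGMT()] preserves it.
#'
#' @param sigs A [SignatureCollection-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGMT <- function(sigs, path) {
  stopifnot(is(sigs, "SignatureCollection"))
  desc <- ifelse(sigs@immune, "immune", "other")
  lines <- mapply(function(nm, d, genes)
    paste(c(nm, d, genes), collapse = "\t"),
    names(sigs@sets), desc, sigs@sets)
  writeLines(unname(lines), path)
  invisible(path)
}
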
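#' Peptide array layouts
#'
#' Describes the geometry of the two array chemistries: the
#' serine/threonine kinase (STK) chip carries 144 reporter peptides in a
#' 12 x 12 grid and the protein tyrosine kinase (PTK) chip carries 196
#' reporter peptides in a 14 x 14 grid.
#'
#' @param chip_type `"STK"` or `"PTK"`.
#' @return An object of class `array_layout`: a list with `chip_type`,
#'   `n_peptides`, `grid_rows`, `grid_cols` and `peptide_ids`.
#' @examples
#' array_layout("STK")$n_peptides  # 144
#' array_layout("PTK")$n_peptides  # 196
#' @export
array_layout <- function(chip_type = c("STK", "PTK")) {
  chip_type <- match.arg(chip_type)
  dim <- switch(chip_type, STK = 12L, PTK = 14L)
  n <- dim * dim
  out <- list(
    chip_type = chip_type,
    n_peptides = n,
    grid_rows = dim,
    grid_cols = dim,
    peptide_ids = sprintf("%s_%03d", chip_type, seq_len(n))
  )
  class(out) <- "array_layout"
  validate_array_layout(out)
  out
}

validate_array_layout <- function(layout) {
  stopifnot(inherits(layout, "array_layout"))
  if (layout$n_peptides != layout$grid_rows * layout$grid_cols)
    stop("array layout: n_peptides must equal grid_rows * grid_cols")
  if (anyDuplicated(layout$peptide_ids))
    stop("array layout: peptide_ids must be unique")
  expected <- switch(layout$chip_type, STK = 144L, PTK = 196L)
  if (layout$n_peptides != expected)
    stop(sprintf("array layout: %s chip must carry %d peptides",
                 layout$chip_type, expected))
  invisible(layout)
}

#' @export
print.array_layout <- function(x, ...) {
  cat(sprintf("<array_layout> %s chip: %d peptides (%d x %d grid)\n",
              x$chip_type, x$n_peptides, x$grid_rows, x$grid_cols))
  invisible(x)
}

# Kinase families used for the bundled synthetic substrate maps; chosen to
# match the families discussed for each chip chemistry (serine/threonine
# families on STK, tyrosine families on PTK).
stk_families <- function() {
  c("ERK", "IKK", "JNK", "P38", "PKD", "RIPK",
    "CAMK2", "PKA", "PKC", "AKT", "GSK3", "CK2")
}

ptk_families <- function() {
  c("CSK", "EGFR", "FAK", "VEGFR", "SRC", "ABL", "JAK",
    "SYK", "RYK", "INSR", "PDGFR", "EPH", "FGFR", "MET")
}

#' Deterministic synthetic kinase-substrate map for a layout
#'
#' Partitions the layout's reporter peptides into equally sized blocks, one
#' per kinase family, and additionally maps every seventh peptide to the
#' following family so that some peptides are multi-mapped (as on real
#' arrays). The map is purely synthetic: it fixes which peptides report on
#' which family so planted activity shifts have a known substrate set.
#'
#' @param layout An [array_layout()].
#' @return A named list of peptide-id character vectors (class
#'   `kinase_map`), one element per family, with attributes `level`
#'   (`"family"`) and `source_name`.
#' @export
demo_kinase_map <- function(layout) {
  validate_array_layout(layout)
  fams <- switch(layout$chip_type, STK = stk_families(), PTK = ptk_families())
  block <- layout$n_peptides / length(fams)
  idx <- rep(seq_along(fams), each = block)
  sets <- split(layout$peptide_ids, fams[idx])
  # cross-mapping: every 7th peptide also reports on the next family
  extra <- seq(7L, layout$n_peptides, by = 7L)
  for (i in extra) {
    fam_next <- fams[(idx[i] %% length(fams)) + 1L]
    sets[[fam_next]] <- union(sets[[fam_next]], layout$peptide_ids[i])
  }
  sets <- sets[fams]
  attr(sets, "level") <- "family"
  attr(sets, "source_name") <- paste0("synthetic_", layout$chip_type, "_map")
  class(sets) <- "kinase_map"
  sets
}

#' Kinase alias and family vocabulary
#'
#' Loads the packaged mapping from kinase aliases to HGNC symbols and from
#' symbols to kinase families. The table is a small curated fixture
#' covering the kinases and families handled by the bundled synthetic
#' maps; it is not a full HGNC download.
#'
#' @return A data frame with columns `alias`, `symbol`, `family`.
#' @export
default_alias_map <- function() {
  path <- system.file("extdata", "kinase_aliases.tsv", package = "kinomepipe")
  if (!nzchar(path)) stop("packaged alias table not found")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
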
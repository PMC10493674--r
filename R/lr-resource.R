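#' Ligand-receptor pairs, complexes and ortholog mapping
#'
#' A ligand-receptor pair couples a ligand unit with a receptor unit; either
#' unit may be a multi-subunit complex written with `+` between gene symbols
#' (e.g. receptor `BMPR1A+ACVR2A`). The canonical `pair_id` is
#' `"L1+L2_R1+R2"`.
#'
#' @name lr_resource
NULL

#' Construct a ligand-receptor pair
#'
#' @param ligand,receptor character scalars; subunits joined with `+`.
#' @return A list of class `lr_pair` with fields `ligand_units`,
#'   `receptor_units` and `pair_id`.
#' @examples
#' lr_pair("BMP7", "BMPR1A+ACVR2A")$pair_id
#' @export
lr_pair <- function(ligand, receptor) {
  lu <- strsplit(ligand, "+", fixed = TRUE)[[1]]
  ru <- strsplit(receptor, "+", fixed = TRUE)[[1]]
  if (length(lu) == 0 || length(ru) == 0 || any(!nzchar(c(lu, ru))))
    stopf("empty ligand or receptor unit in '%s' / '%s'", ligand, receptor)
  if (anyDuplicated(lu) || anyDuplicated(ru))
    stopf("duplicated subunit within one side of '%s_%s'", ligand, receptor)
  structure(list(ligand_units = lu, receptor_units = ru,
                 pair_id = paste0(paste(lu, collapse = "+"), "_",
                                  paste(ru, collapse = "+"))),
            class = "lr_pair")
}

#' Parse a canonical pair id back into a pair
#'
#' @param pair_id string of the form `"L1+L2_R1+R2"`.
#' @return An [lr_pair()].
#' @export
parse_pair_id <- function(pair_id) {
  halves <- strsplit(pair_id, "_", fixed = TRUE)[[1]]
  if (length(halves) != 2) stopf("malformed pair id '%s'", pair_id)
  lr_pair(halves[1], halves[2])
}

#' Load a ligand-receptor database from TSV
#'
#' Expects columns `ligand` and `receptor`; `+` joins complex subunits.
#' Pairs are deduplicated by `pair_id`, keeping first occurrence in input
#' order. A malformed row (empty field) is an error reporting the line.
#'
#' @param path TSV file path.
#' @return List of [lr_pair()] objects.
#' @export
load_lr_database <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(tab)))
    stopf("%s must have columns 'ligand' and 'receptor'", path)
  bad <- which(is.na(tab$ligand) | is.na(tab$receptor) |
                 !nzchar(tab$ligand) | !nzchar(tab$receptor))
  if (length(bad))
    stopf("empty ligand/receptor field at line %d of %s", bad[1] + 1L, path)
  pairs <- Map(lr_pair, tab$ligand, tab$receptor)
  ids <- vapply(pairs, `[[`, "", "pair_id")
  unname(pairs[!duplicated(ids)])
}

#' Map pairs across species with an ortholog table
#'
#' Every subunit of every pair is mapped through a two-column table
#' (`source` -> `target`). Pairs with any unmapped subunit are dropped; a
#' one-to-many source symbol keeps the first mapping in table order with a
#' warning.
#'
#' @param pairs list of [lr_pair()].
#' @param ortholog_table data.frame with columns `source`, `target`.
#' @return List with `pairs` (mapped) and `n_dropped`.
#' @export
map_orthologs <- function(pairs, ortholog_table) {
  if (!all(c("source", "target") %in% names(ortholog_table)))
    stopf("ortholog_table needs columns 'source' and 'target'")
  dup <- duplicated(ortholog_table$source)
  if (any(dup)) {
    warnf("one-to-many ortholog mapping for %s; keeping first",
          paste(unique(ortholog_table$source[dup]), collapse = ", "))
    ortholog_table <- ortholog_table[!dup, , drop = FALSE]
  }
  lookup <- stats::setNames(ortholog_table$target, ortholog_table$source)
  mapped <- list()
  n_dropped <- 0L
  for (p in pairs) {
    lu <- unname(lookup[p$ligand_units])
    ru <- unname(lookup[p$receptor_units])
    if (anyNA(lu) || anyNA(ru)) {
      n_dropped <- n_dropped + 1L
      next
    }
    mapped[[length(mapped) + 1L]] <-
      lr_pair(paste(lu, collapse = "+"), paste(ru, collapse = "+"))
  }
  list(pairs = mapped, n_dropped = n_dropped)
}

#' Aggregate subunit expression into a complex-level value
#'
#' Geometric mean of the subunit values, so one absent subunit abolishes the
#' complex (mass-action intuition). A single-gene unit is returned as is.
#'
#' @param unit_values non-negative numeric vector, one value per subunit.
#' @return Non-negative scalar.
#' @examples
#' complex_expression(c(4, 1)) # 2
#' @export
complex_expression <- function(unit_values) {
  if (any(unit_values < 0)) stopf("negative subunit expression")
  if (any(unit_values == 0)) return(0)
  exp(mean(log(unit_values)))
}
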
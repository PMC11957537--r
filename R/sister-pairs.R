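#' Extract sister-cell pairs from a lineage forest
#'
#' Sister pairs (two daughters of the same mother) are the unit of the
#' asymmetry statistics Cg, CT and Cs. One pair is returned per mother with
#' exactly two tracked daughters; mothers with fewer tracked daughters are
#' excluded. Output order is deterministic (sorted by `mother_id`, daughters
#' ordered by `cell_id` within a pair), so results are invariant under
#' permutation of the input rows.
#'
#' @param x a [LineageTable-class].
#' @param generation restrict to pairs whose sisters are at this generation
#'   (integer), or `"all"` (default).
#' @return `data.frame` with one row per pair: `mother_id`, `generation`,
#'   `cell_a`/`cell_b`, `fate_a`/`fate_b`, elongation rates `r_a`/`r_b`
#'   (1/min; least-squares fit of `log(volume)` vs time, `NA` when a sister
#'   has fewer than 3 observations), division times `T_a`/`T_b` (min; `NA`
#'   unless divided), and birth volumes `Vb_a`/`Vb_b` (um^3).
#' @seealso [asymmetrySummary()]
#' @export
extractSisterPairs <- function(x, generation = "all") {
  stopifnot(is(x, "LineageTable"))
  cc <- x@cells
  kids <- cc[!is.na(cc$parent_id), , drop = FALSE]
  if (!identical(generation, "all"))
    kids <- kids[kids$generation == as.integer(generation), , drop = FALSE]
  empty <- data.frame(mother_id = character(), generation = integer(),
                      cell_a = character(), cell_b = character(),
                      fate_a = character(), fate_b = character(),
                      r_a = numeric(), r_b = numeric(),
                      T_a = numeric(), T_b = numeric(),
                      Vb_a = numeric(), Vb_b = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(kids) == 0L) return(empty)
  byMother <- split(kids$cell_id, kids$parent_id)
  byMother <- byMother[lengths(byMother) == 2L]
  if (length(byMother) == 0L) return(empty)
  mothers <- sort(names(byMother))

  seriesByCell <- split(x@series[c("time", "volume")], x@series$cell_id)
  rateOf <- function(id) {
    s <- seriesByCell[[id]]
    if (is.null(s) || nrow(s) < 3) return(NA_real_)
    fitElongationRate(s$time, s$volume)$r
  }
  rows <- lapply(mothers, function(m) {
    pair <- sort(byMother[[m]])
    i <- match(pair, cc$cell_id)
    data.frame(mother_id = m, generation = cc$generation[i[1]],
               cell_a = pair[1], cell_b = pair[2],
               fate_a = cc$fate[i[1]], fate_b = cc$fate[i[2]],
               r_a = rateOf(pair[1]), r_b = rateOf(pair[2]),
               T_a = cc$division_time[i[1]] - cc$birth_time[i[1]],
               T_b = cc$division_time[i[2]] - cc$birth_time[i[2]],
               Vb_a = cc$birth_volume[i[1]], Vb_b = cc$birth_volume[i[2]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
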
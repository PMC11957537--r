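#' Accessors for LineageTable
#'
#' `cells()` returns the per-cell summary table (one row per tracked cell),
#' `volumeSeries()` the long (cell, time, volume) observation table, and
#' `metadata()` the provenance list.
#'
#' @param x a [LineageTable-class].
#' @return `data.frame` (accessors) or `list` (`metadata`).
#' @aliases cells volumeSeries metadata,LineageTable-method
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))

#' @rdname cells
#' @export
setGeneric("volumeSeries", function(x) standardGeneric("volumeSeries"))

#' @rdname cells
#' @export
setMethod("cells", "LineageTable", function(x) x@cells)

#' @rdname cells
#' @export
setMethod("volumeSeries", "LineageTable", function(x) x@series)

#' @rdname cells
#' @export
setMethod("metadata", "LineageTable", function(x, ...) x@metadata)

#' @describeIn cells number of tracked cells.
#' @export
setMethod("length", "LineageTable", function(x) nrow(x@cells))

setMethod("show", "LineageTable", function(object) {
  cc <- object@cells
  nf <- sum(is.na(cc$parent_id))
  gmax <- if (nrow(cc)) max(cc$generation) else 0L
  cat(sprintf(
    "LineageTable: %d cells (%d founders, generations 0-%d), %d observations\n",
    nrow(cc), nf, gmax, nrow(object@series)))
  if (nrow(cc)) {
    tab <- table(factor(cc$fate, levels = CELL_FATES))
    cat(sprintf("  fates: %s\n",
                paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  }
  src <- object@metadata$source
  if (!is.null(src)) cat("  source:", src, "\n")
  invisible(NULL)
})

setMethod("show", "SimulationConfig", function(object) {
  sv <- object@survival
  cat("SimulationConfig\n")
  cat(sprintf("  r0 = %.4g /min, dV0 = %.3g um^3 (cv %.2g)\n",
              object@r0, object@dV0, object@cv_dV))
  cat(sprintf("  sigma_g = %.4g (Cg ~ %.3g), sigma_s = %.4g (Cs ~ %.3g)\n",
              object@sigma_g, expectedCg(object@sigma_g),
              object@sigma_s, expectedCs(object@sigma_s)))
  cat(sprintf("  survival: p_mid %.2f on [%.3g, %.3g] um^3, steepness %.3g\n",
              sv["p_mid"], sv["V_lo"], sv["V_hi"], sv["steepness"]))
  cat(sprintf("  %d founders x %d generations, frame_dt %g min, seed %d\n",
              object@n_founders, object@n_generations, object@frame_dt,
              object@seed))
  invisible(NULL)
})
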
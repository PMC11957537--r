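# Small in-code fixtures: long-format frame tables the tracking reader
# consumes, built by hand so expected values are enumerable.

frameRows <- function(id, parent, times, volumes) {
  data.frame(cell_id = id,
             parent_id = if (is.na(parent)) NA_character_ else parent,
             time = times, volume = volumes, stringsAsFactors = FALSE)
}

# founder growing 2 -> 4 um^3 over 30 min, dividing into two equal daughters
# that are then tracked for a few frames
tinyForestSeries <- function() {
  t0 <- seq(0, 30, 5)
  rbind(
    frameRows("F1", NA, t0, 2 * exp(log(2) / 30 * t0)),
    frameRows("F1.1", "F1", seq(30, 50, 5), 2 * exp(0.01 * seq(0, 20, 5))),
    frameRows("F1.2", "F1", seq(30, 50, 5), 2 * exp(0.012 * seq(0, 20, 5))))
}

tinyForest <- function(fate = NULL) {
  makeLineageTable(tinyForestSeries(), fate = fate,
                   metadata = list(frame_dt = 5))
}

# forest with explicit fates for survival / asymmetry statistics:
# nDiv divided + nArr arrested daughters of distinct mothers
fateForest <- function(nDiv, nArr, tau = 60, vb = 2) {
  rows <- list()
  fates <- character()
  for (i in seq_len(nDiv + nArr)) {
    m <- sprintf("M%03d", i)
    d <- paste0(m, ".1")
    rows[[length(rows) + 1]] <-
      frameRows(m, NA, c(0, 30, 60), vb * exp(0.01 * c(0, 30, 60)))
    fates[m] <- "divided"
    divided <- i <= nDiv
    if (divided) {
      rows[[length(rows) + 1]] <-
        frameRows(d, m, 60 + seq(0, tau, 20), vb * exp(0.01 * seq(0, tau, 20)))
      fates[d] <- "divided"
    } else {
      rows[[length(rows) + 1]] <-
        frameRows(d, m, 60 + c(0, 20, 40), rep(vb, 3))
      fates[d] <- "arrested"
    }
  }
  makeLineageTable(do.call(rbind, rows), fate = fates,
                   metadata = list(frame_dt = 20))
}

# brute-force RSS grid-search oracle for the exponential rate fit
gridSearchRate <- function(time, volume, grid = seq(-0.05, 0.08, by = 1e-4)) {
  tt <- time - time[1]
  y <- log(volume)
  rss <- vapply(grid, function(r) {
    a <- mean(y - r * tt)
    sum((y - a - r * tt)^2)
  }, numeric(1))
  grid[which.min(rss)]
}
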
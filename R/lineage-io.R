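#' Build a LineageTable from a long per-frame table
#'
#' Assembles and validates a [LineageTable-class] from the long format used by
#' tracking tools: one row per (cell, frame) with the cell's parent repeated on
#' every row. Per-cell summaries (generation, birth/division time and volume)
#' are derived from the observations.
#'
#' @param series `data.frame` with columns `cell_id`, `parent_id` (`NA` or
#'   `""` for founders), `time` (min), `volume` (um^3), and optionally `fate`.
#' @param fate optional named character vector (names = cell ids) overriding /
#'   replacing a `fate` column. When absent, fate is inferred: a cell with
#'   daughters divided; otherwise arrested if its last observation precedes the
#'   end of the table by at least `arrestThreshold` (no division during the
#'   subsequent observation window), else censored.
#' @param metadata provenance list; `metadata$frame_dt` (min) sets the
#'   tolerance for daughter-birth/mother-division agreement (default 5).
#' @param arrestThreshold minutes of subsequent observation without division
#'   required to score a non-dividing cell as arrested (default 300, i.e. 5 h).
#' @return a validated [LineageTable-class].
#' @export
makeLineageTable <- function(series, fate = NULL, metadata = list(),
                             arrestThreshold = 300) {
  stopifnot(is.data.frame(series))
  miss <- setdiff(c("cell_id", "parent_id", "time", "volume"), names(series))
  if (length(miss))
    stop("series is missing columns: ", paste(miss, collapse = ", "))
  series$cell_id <- as.character(series$cell_id)
  series$parent_id <- as.character(series$parent_id)
  series$parent_id[!is.na(series$parent_id) &
                   series$parent_id == ""] <- NA_character_
  fateCol <- NULL
  if (!is.null(series$fate)) fateCol <- as.character(series$fate)

  ord <- order(match(series$cell_id, unique(series$cell_id)), series$time)
  series <- series[ord, , drop = FALSE]
  if (!is.null(fateCol)) fateCol <- fateCol[ord]
  ids <- unique(series$cell_id)
  first <- !duplicated(series$cell_id)
  last <- !duplicated(series$cell_id, fromLast = TRUE)

  parent <- series$parent_id[first]
  if (any(vapply(split(series$parent_id, series$cell_id)[ids],
                 function(p) length(unique(p)) > 1, logical(1))))
    stop("integrity error: a cell_id appears with more than one parent_id")
  names(parent) <- ids

  # generations by walking up the forest
  gen <- rep(NA_integer_, length(ids))
  names(gen) <- ids
  gen[is.na(parent)] <- 0L
  repeat {
    todo <- is.na(gen) & parent %in% ids[!is.na(gen)]
    if (!any(todo)) break
    gen[todo] <- gen[parent[todo]] + 1L
  }
  if (anyNA(gen))
    stop("integrity error: parent_id does not resolve for cell(s) ",
         paste(ids[is.na(gen)], collapse = ", "))

  hasKids <- ids %in% parent
  endT <- max(series$time)
  lastT <- setNames(series$time[last], ids)
  if (is.null(fate)) {
    if (!is.null(fateCol)) {
      fate <- setNames(fateCol[first], ids)
    } else {
      fate <- ifelse(hasKids, "divided",
                     ifelse(endT - lastT >= arrestThreshold,
                            "arrested", "censored"))
      names(fate) <- ids
    }
  } else fate <- fate[ids]
  if (!all(fate %in% CELL_FATES))
    stop("fate must be one of ", paste(CELL_FATES, collapse = "/"))
  if (any(hasKids & fate != "divided"))
    stop("integrity error: cells with daughters must have fate 'divided'")

  div <- fate == "divided"
  cellsDf <- data.frame(
    cell_id = ids,
    parent_id = unname(parent),
    generation = unname(gen),
    birth_time = unname(setNames(series$time[first], ids)[ids]),
    division_time = ifelse(div, unname(lastT[ids]), NA_real_),
    fate = unname(fate[ids]),
    birth_volume = unname(setNames(series$volume[first], ids)[ids]),
    division_volume = ifelse(div, unname(setNames(series$volume[last],
                                                  ids)[ids]), NA_real_),
    stringsAsFactors = FALSE)
  rownames(cellsDf) <- NULL
  seriesDf <- data.frame(cell_id = series$cell_id, time = series$time,
                         volume = series$volume, stringsAsFactors = FALSE)
  rownames(seriesDf) <- NULL
  new("LineageTable", cells = cellsDf, series = seriesDf, metadata = metadata)
}

#' Read / write lineage tables as commented CSV
#'
#' The on-disk format is a long UTF-8 CSV, one row per (cell, frame), with
#' columns `cell_id, parent_id, fate, time, volume` and a commented header of
#' `# key=value` lines carrying provenance metadata (JSON-encoded values).
#' `readLineageTable()` validates the file and reports violations with the
#' offending data row numbers; `writeLineageTable()` writes numbers at full
#' double precision so that read-after-write reproduces the table field for
#' field.
#'
#' @param path file path.
#' @param arrestThreshold passed to [makeLineageTable()] when the file has no
#'   `fate` column.
#' @return `readLineageTable` returns a [LineageTable-class];
#'   `writeLineageTable` returns `path` invisibly.
#' @export
readLineageTable <- function(path, arrestThreshold = 300) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  metaLines <- grep("^#", lines, value = TRUE)
  metadata <- list()
  for (ml in metaLines) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- trimws(substr(kv, 1, eq - 1))
      val <- trimws(substr(kv, eq + 1, nchar(kv)))
      metadata[[key]] <- tryCatch(jsonlite::fromJSON(val),
                                  error = function(e) val)
    }
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                 colClasses = c(cell_id = "character",
                                parent_id = "character"))
  need <- c("cell_id", "parent_id", "time", "volume")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "))
  df$parent_id[!is.na(df$parent_id) & df$parent_id == ""] <- NA_character_

  # row-numbered integrity checks (rows count data rows, header excluded)
  rowno <- seq_len(nrow(df))
  bad <- which(!is.finite(df$time) | !is.finite(df$volume) | df$volume <= 0)
  if (length(bad))
    stop("integrity error: non-finite time or non-positive volume at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  orphan <- !is.na(df$parent_id) & !(df$parent_id %in% df$cell_id)
  if (any(orphan))
    stop("integrity error: parent_id '",
         df$parent_id[which(orphan)[1]], "' at row ",
         which(orphan)[1], " does not match any cell_id")
  ordRows <- split(rowno, df$cell_id)
  for (rw in ordRows) {
    tt <- df$time[rw]
    if (any(diff(tt) <= 0))
      stop("integrity error: non-monotone times for cell '",
           df$cell_id[rw[1]], "' at row ", rw[which(diff(tt) <= 0)[1] + 1])
    pp <- df$parent_id[rw]
    if (length(unique(pp)) > 1)
      stop("integrity error: cell_id '", df$cell_id[rw[1]],
           "' redefined with a different parent_id at row ",
           rw[which(pp != pp[1])[1]],
           " (duplicated cell_id?)")
  }
  makeLineageTable(df, metadata = metadata, arrestThreshold = arrestThreshold)
}

#' @rdname readLineageTable
#' @param x a [LineageTable-class].
#' @export
writeLineageTable <- function(x, path) {
  stopifnot(is(x, "LineageTable"))
  validObject(x)
  md <- x@metadata
  hdr <- vapply(names(md), function(k)
    sprintf("# %s=%s", k,
            as.character(jsonlite::toJSON(md[[k]], auto_unbox = TRUE,
                                          digits = NA))),
    character(1))
  cc <- x@cells
  ss <- x@series
  idx <- match(ss$cell_id, cc$cell_id)
  out <- data.frame(cell_id = ss$cell_id,
                    parent_id = ifelse(is.na(cc$parent_id[idx]), "",
                                       cc$parent_id[idx]),
                    fate = cc$fate[idx],
                    time = sprintf("%.17g", ss$time),
                    volume = sprintf("%.17g", ss$volume),
                    stringsAsFactors = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(hdr)) writeLines(unname(hdr), con)
  writeLines(paste(names(out), collapse = ","), con)
  writeLines(do.call(paste, c(out, sep = ",")), con)
  invisible(path)
}

#' Write a results table as TSV with a commented provenance header
#'
#' Small helper used to persist analysis outputs: a plain TSV preceded by
#' `# key=value` comment lines (package version is always included).
#'
#' @param df `data.frame` of results.
#' @param path output path.
#' @param provenance named list appended to the header.
#' @return `path`, invisibly.
#' @export
writeResultsTSV <- function(df, path, provenance = list()) {
  provenance$package <- paste0("LineageHomeo ",
                               as.character(packageVersion("LineageHomeo")))
  hdr <- vapply(names(provenance), function(k)
    sprintf("# %s=%s", k,
            as.character(jsonlite::toJSON(provenance[[k]],
                                          auto_unbox = TRUE, digits = NA))),
    character(1))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(unname(hdr), con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}
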
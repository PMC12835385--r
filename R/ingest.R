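# Reading, writing and deduplicating FAERS-style quarterly extracts.

TABLE_NAMES <- c("demo", "drug", "reac", "ther", "indi", "outc", "rpsr")

#' Read one FAERS-style quarter
#'
#' Reads the seven dollar-delimited ASCII tables of a quarterly extract
#' (DEMO, DRUG, REAC, THER, INDI, OUTC, RPSR), resolves legacy column
#' aliases per the dialect, and returns a validated `faers_tables` object.
#' Raw text fields are preserved as character columns. Rows with the wrong
#' field count and non-DEMO rows whose report identifier is absent from DEMO
#' are counted in the ingest log (`attr(x, "log")`), not silently dropped
#' from the tally.
#'
#' @param paths named character vector/list of file paths (names in
#'   `demo, drug, reac, ther, indi, outc, rpsr`), or a single directory
#'   containing files whose names start with those table names.
#' @param dialect a [faers_dialect()].
#' @param quarter label stored on the result (e.g. `"24Q4"`).
#' @return a `faers_tables` object: a named list of character data frames
#'   with an ingest log attribute.
#' @export
read_faers_quarter <- function(paths, dialect = faers_dialect(),
                               quarter = NA_character_) {
  if (length(paths) == 1 && is.character(paths) && dir.exists(paths)) {
    dirp <- paths
    paths <- lapply(TABLE_NAMES, function(tb) {
      f <- list.files(dirp, pattern = paste0("^", tb), full.names = TRUE,
                      ignore.case = TRUE)
      if (length(f) == 0) stop_config("no file for table '%s' in %s", tb, dirp)
      f[1]
    })
    names(paths) <- TABLE_NAMES
  }
  missing_tb <- setdiff(TABLE_NAMES, names(paths))
  if (length(missing_tb))
    stop_config("missing table path(s): %s", paste(missing_tb, collapse = ", "))

  log <- list()
  tabs <- list()
  for (tb in TABLE_NAMES) {
    path <- paths[[tb]]
    if (!file.exists(path)) {
      stop(errorCondition(sprintf("cannot read %s table: file '%s' not found",
                                  tb, path),
                          class = c("faersignal_io_error", "error")))
    }
    parsed <- read_delim_table(path, dialect$delim)
    tabs[[tb]] <- resolve_columns(parsed$data, dialect$columns[[tb]], tb)
    log[[tb]] <- list(rows = nrow(parsed$data), malformed = parsed$malformed)
  }
  as_faers_tables(tabs, quarter = quarter, log = log)
}

# Parse one $-delimited file; count rows whose field count disagrees with
# the header (they are kept, short rows padded with NA, and reported).
read_delim_table <- function(path, delim) {
  nf <- utils::count.fields(path, sep = delim, quote = "", comment.char = "")
  malformed <- sum(nf[-1] != nf[1])
  dat <- utils::read.table(path, sep = delim, quote = "", comment.char = "",
                           header = TRUE, colClasses = "character",
                           fill = TRUE, blank.lines.skip = TRUE,
                           check.names = FALSE, strip.white = FALSE,
                           na.strings = NULL)
  list(data = dat, malformed = malformed)
}

# Map raw header names onto canonical ones using the dialect aliases;
# a mandatory column with no alias present is a configuration error.
resolve_columns <- function(df, colspec, table_name) {
  hdr <- toupper(names(df))
  out <- df
  names(out) <- hdr
  for (canon in names(colspec)) {
    hit <- intersect(colspec[[canon]], hdr)
    if (length(hit) == 0) {
      stop_config("table '%s' is missing mandatory column '%s'",
                  table_name, canon)
    }
    if (hit[1] != canon) names(out)[match(hit[1], names(out))] <- canon
  }
  out[, names(colspec), drop = FALSE]
}

as_faers_tables <- function(tabs, quarter = NA_character_, log = list()) {
  demo_ids <- tabs$demo$PRIMARYID
  for (tb in setdiff(TABLE_NAMES, "demo")) {
    orphan <- !(tabs[[tb]]$PRIMARYID %in% demo_ids)
    if (any(orphan)) {
      log[[tb]]$orphans <- sum(orphan)
      tabs[[tb]] <- tabs[[tb]][!orphan, , drop = FALSE]
      rownames(tabs[[tb]]) <- NULL
    }
  }
  structure(tabs, quarter = quarter, log = log, class = "faers_tables")
}

#' @export
print.faers_tables <- function(x, ...) {
  cat("FAERS-style quarterly tables",
      if (!is.na(attr(x, "quarter"))) sprintf("(%s)", attr(x, "quarter")),
      "\n")
  for (tb in TABLE_NAMES)
    cat(sprintf("  %-5s %6d rows\n", tb, nrow(x[[tb]])))
  invisible(x)
}

#' Write one FAERS-style quarter
#'
#' Writes the seven tables in the same dollar-delimited dialect the reader
#' accepts, one file per table (`<table><quarter>.txt`).
#'
#' @param tables a `faers_tables` object.
#' @param dir output directory (created if needed).
#' @param dialect a [faers_dialect()].
#' @return named vector of written file paths, invisibly.
#' @export
write_faers_quarter <- function(tables, dir, dialect = faers_dialect()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  q <- attr(tables, "quarter")
  suffix <- if (is.null(q) || is.na(q)) "" else tolower(q)
  paths <- character(0)
  for (tb in TABLE_NAMES) {
    path <- file.path(dir, paste0(tb, suffix, ".txt"))
    utils::write.table(tables[[tb]], path, sep = dialect$delim, quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    paths[tb] <- path
  }
  invisible(paths)
}

#' Combine multiple quarters with replacement semantics
#'
#' FAERS re-publishes amended reports: when the same PRIMARYID appears in
#' more than one quarter, the record from the later quarter replaces the
#' earlier one (in every table) before deduplication.
#'
#' @param quarters list of `faers_tables`, in chronological order.
#' @return one merged `faers_tables` object.
#' @export
combine_quarters <- function(quarters) {
  stopifnot(length(quarters) >= 1)
  if (length(quarters) == 1) return(quarters[[1]])
  merged <- lapply(TABLE_NAMES, function(tb) {
    parts <- lapply(quarters, `[[`, tb)
    qidx <- rep(seq_along(parts), vapply(parts, nrow, 0L))
    df <- do.call(rbind, parts)
    # keep only rows whose PRIMARYID's latest quarter equals their own
    latest <- tapply(qidx, df$PRIMARYID, max)
    keep <- qidx == latest[df$PRIMARYID]
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  names(merged) <- TABLE_NAMES
  as_faers_tables(merged,
                  quarter = paste(vapply(quarters, function(q)
                    as.character(attr(q, "quarter")), ""), collapse = "+"))
}

#' Deduplicate case versions by CASEID / FDA_DT / PRIMARYID
#'
#' A FAERS case may be submitted several times; analyses keep one report per
#' case: the version with the most recent FDA receipt date (`FDA_DT`), and
#' among ties on (`CASEID`, `FDA_DT`) the version with the highest
#' `PRIMARYID`. Records whose `FDA_DT` does not parse as a calendar date are
#' quarantined with a reason and never selected. The rule is deterministic,
#' independent of input row order, and idempotent.
#'
#' @param demo data frame with columns `PRIMARYID`, `CASEID`, `FDA_DT`
#'   (a `faers_tables` object is also accepted, its DEMO table is used).
#' @return list with `kept` (character vector of retained PRIMARYIDs),
#'   `dropped` (superseded versions), and `quarantined` (data frame of
#'   invalid records with a `reason` column).
#' @export
faers_dedup <- function(demo) {
  if (inherits(demo, "faers_tables")) demo <- demo$demo
  need <- c("PRIMARYID", "CASEID", "FDA_DT")
  if (!all(need %in% names(demo)))
    stop_config("deduplication needs columns %s", paste(need, collapse = ", "))

  pid <- as.character(demo$PRIMARYID)
  cid <- as.character(demo$CASEID)
  fdt <- parse_faers_date(demo$FDA_DT)

  bad <- is.na(fdt)
  quarantined <- demo[bad, need, drop = FALSE]
  if (nrow(quarantined)) quarantined$reason <- "invalid FDA_DT"
  rownames(quarantined) <- NULL

  pid <- pid[!bad]; cid <- cid[!bad]; fdt <- fdt[!bad]
  if (length(pid) == 0) {
    return(list(kept = character(0), dropped = character(0),
                quarantined = quarantined))
  }
  # sort by (caseid, fda_dt, primaryid-as-number) and keep the last per case
  pnum <- suppressWarnings(as.numeric(pid))
  pnum[is.na(pnum)] <- -Inf
  o <- order(cid, fdt, pnum, pid)
  cid_o <- cid[o]
  last <- !duplicated(cid_o, fromLast = TRUE)
  kept <- pid[o][last]
  list(kept = kept, dropped = setdiff(pid, kept), quarantined = quarantined)
}
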
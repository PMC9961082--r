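#' Write and read spectra matrices
#'
#' Two plain-text dialects are supported. `"matrix-csv"`: the first row
#' holds the column headers `sample_id`, `replicate_id` followed by the
#' wavenumbers; each subsequent row is one spectrum. `"jcamp-dx"`: one
#' JCAMP-DX block per spectrum with `##XYDATA=(X++(Y..Y))` in plain AFFN
#' numbers (`XFACTOR = YFACTOR = 1`); multiple blocks concatenated in one
#' file. Both round-trip absorbances to at least 12 significant digits.
#'
#' On reading, a descending wavenumber axis is normalized to ascending with
#' the columns permuted accordingly. Ragged rows, non-numeric cells,
#' non-finite values and a non-monotone axis abort with an error naming the
#' offending row or column; nothing is ever silently imputed.
#'
#' @param block a [SpectraBlock-class] (or [NirDataset-class], whose block
#'   is written).
#' @param path file path.
#' @param dialect `"matrix-csv"` or `"jcamp-dx"`.
#' @return `writeSpectra()` returns `path` invisibly; `readSpectra()`
#'   returns a [SpectraBlock-class].
#' @examples
#' blk <- spectraBlock(seq(4000, 4040, 4), matrix(rnorm(22), 2))
#' f <- tempfile(fileext = ".csv")
#' writeSpectra(blk, f)
#' all.equal(absorbance(readSpectra(f)), absorbance(blk))
#' @export
writeSpectra <- function(block, path, dialect = c("matrix-csv", "jcamp-dx")) {
  dialect <- match.arg(dialect)
  if (is(block, "NirDataset")) block <- block@block
  stopifnot(is(block, "SpectraBlock"))
  if (dialect == "matrix-csv") {
    header <- paste(c("sample_id", "replicate_id",
                      sprintf("%.10g", block@wavenumbers)), collapse = ",")
    rows <- vapply(seq_len(nrow(block@absorbance)), function(i) {
      paste(c(block@sampleIds[i], block@replicateIds[i],
              sprintf("%.15g", block@absorbance[i, ])), collapse = ",")
    }, "")
    writeLines(c(header, rows), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(block@absorbance))) {
      .writeJcampBlock(con, block@wavenumbers, block@absorbance[i, ],
                       block@sampleIds[i], block@replicateIds[i])
    }
  }
  invisible(path)
}

.writeJcampBlock <- function(con, wn, y, sid, rid) {
  writeLines(c(
    sprintf("##TITLE=sample %s replicate %d", sid, rid),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    sprintf("##$SAMPLE ID=%s", sid),
    sprintf("##$REPLICATE ID=%d", rid),
    "##XUNITS=1/CM",
    "##YUNITS=ABSORBANCE",
    "##XFACTOR=1",
    "##YFACTOR=1",
    sprintf("##FIRSTX=%.10g", wn[1L]),
    sprintf("##LASTX=%.10g", wn[length(wn)]),
    sprintf("##NPOINTS=%d", length(wn)),
    "##XYDATA=(X++(Y..Y))"
  ), con)
  idx <- split(seq_along(y), ceiling(seq_along(y) / 4L))
  for (ii in idx) {
    writeLines(paste(c(sprintf("%.10g", wn[ii[1L]]),
                       sprintf("%.15g", y[ii])), collapse = " "), con)
  }
  writeLines("##END=", con)
}

#' @rdname writeSpectra
#' @export
readSpectra <- function(path, dialect = c("matrix-csv", "jcamp-dx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "matrix-csv") .readMatrixCsv(path) else .readJcamp(path)
}

.readMatrixCsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("spectra file must have a header and data rows")
  cells <- strsplit(lines, ",", fixed = TRUE)
  width <- length(cells[[1L]])
  if (width < 4L) stop("header must hold sample_id, replicate_id and >= 2 wavenumbers")
  ragged <- which(lengths(cells) != width)
  if (length(ragged)) {
    stop("ragged row(s): ", paste(ragged, collapse = ", "),
         " (expected ", width, " cells)")
  }
  wn <- suppressWarnings(as.numeric(cells[[1L]][-(1:2)]))
  if (any(is.na(wn))) {
    stop("non-numeric wavenumber in header column(s): ",
         paste(which(is.na(wn)) + 2L, collapse = ", "))
  }
  d <- diff(wn)
  if (!(all(d > 0) || all(d < 0))) stop("wavenumber axis is not strictly monotone")
  body <- cells[-1L]
  sid <- vapply(body, `[`, "", 1L)
  rid <- suppressWarnings(as.integer(vapply(body, `[`, "", 2L)))
  if (any(is.na(rid))) {
    stop("non-numeric replicate_id in row(s): ",
         paste(which(is.na(rid)) + 1L, collapse = ", "))
  }
  ab <- matrix(NA_real_, length(body), length(wn))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-(1:2)]))
    if (any(is.na(v))) {
      stop(sprintf("non-numeric or missing absorbance at row %d, column %d",
                   i + 1L, which(is.na(v))[1L] + 2L))
    }
    ab[i, ] <- v
  }
  if (any(!is.finite(ab))) stop("non-finite absorbance values; load aborted")
  spectraBlock(wn, ab, sampleIds = sid, replicateIds = rid)
}

.readJcamp <- function(path) {
  lines <- readLines(path)
  starts <- grep("^##TITLE=", lines)
  if (!length(starts)) stop("no JCAMP-DX blocks found")
  ends <- grep("^##END=", lines)
  if (length(ends) != length(starts)) stop("unbalanced JCAMP-DX blocks")
  specs <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    chunk <- lines[starts[b]:ends[b]]
    getLabel <- function(lab) {
      hit <- grep(paste0("^##\\$?", lab, "="), chunk, value = TRUE)
      if (!length(hit)) return(NA_character_)
      sub("^[^=]*=", "", hit[1L])
    }
    npt <- as.integer(getLabel("NPOINTS"))
    xf <- as.numeric(getLabel("XFACTOR"))
    yf <- as.numeric(getLabel("YFACTOR"))
    if (is.na(xf)) xf <- 1
    if (is.na(yf)) yf <- 1
    xyAt <- grep("^##XYDATA=", chunk)
    if (!length(xyAt)) stop("block ", b, ": missing XYDATA")
    dataLines <- chunk[(xyAt + 1L):(length(chunk) - 1L)]
    dataLines <- dataLines[!grepl("^##", dataLines) & nzchar(trimws(dataLines))]
    xs <- numeric(0)
    ys <- numeric(0)
    for (dl in dataLines) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(dl), "[ \t]+")[[1L]]))
      if (any(is.na(v)) || length(v) < 2L) {
        stop("block ", b, ": malformed XYDATA line: ", dl)
      }
      xs <- c(xs, v[1L])
      ys <- c(ys, v[-1L])
    }
    if (!is.na(npt) && length(ys) != npt) {
      stop("block ", b, ": NPOINTS=", npt, " but ", length(ys), " Y values read")
    }
    firstx <- as.numeric(getLabel("FIRSTX"))
    lastx <- as.numeric(getLabel("LASTX"))
    if (is.na(firstx) || is.na(lastx)) {
      firstx <- xs[1L] * xf
      lastx <- xs[length(xs)] * xf # approximate when line starts are all we have
    }
    wn <- seq(firstx, lastx, length.out = length(ys))
    specs[[b]] <- list(
      sid = getLabel("SAMPLE ID"), rid = as.integer(getLabel("REPLICATE ID")),
      wn = wn, y = ys * yf
    )
  }
  wn <- specs[[1L]]$wn
  for (b in seq_along(specs)) {
    if (length(specs[[b]]$wn) != length(wn) ||
        max(abs(specs[[b]]$wn - wn)) > 1e-6) {
      stop("block ", b, ": wavenumber axis differs from the first block")
    }
  }
  ab <- do.call(rbind, lapply(specs, `[[`, "y"))
  if (any(!is.finite(ab))) stop("non-finite absorbance values; load aborted")
  sid <- vapply(specs, `[[`, "", "sid")
  if (any(is.na(sid))) sid <- as.character(seq_along(specs))
  rid <- vapply(specs, function(s) s$rid, 0L)
  if (any(is.na(rid))) rid <- stats::ave(seq_along(sid), sid, FUN = seq_along)
  spectraBlock(wn, ab, sampleIds = sid, replicateIds = rid)
}

#' Write and read mixture composition tables
#'
#' Plain comma-separated tables mirroring the laboratory design columns
#' (sample id, the four ingredient masses in g, the two stock premix
#' concentrations in mg/kg, derived excipient percentages and API
#' concentration).
#'
#' @param design data.frame as returned by [mixtureDesign()].
#' @param path file path.
#' @return `writeComposition()` returns `path` invisibly;
#'   `readComposition()` returns the data.frame.
#' @export
writeComposition <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeComposition
#' @export
readComposition <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, check.names = TRUE)
  need <- c("sample_id", "mass_starch", "mass_lactose", "mass_mix_a",
            "mass_mix_b")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("composition table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(d$conc_stock_a)) d$conc_stock_a <- 31964
  if (is.null(d$conc_stock_b)) d$conc_stock_b <- 32395
  d
}

#' Join spectra with a composition table into a dataset
#'
#' Matches every spectrum's sample id against the composition table and
#' attaches the mass-derived API concentration (full precision) as the
#' response; replicate spectra of one sample share one response value.
#'
#' @param block a [SpectraBlock-class].
#' @param composition data.frame with one row per sample
#'   (see [readComposition()]).
#' @return a [NirDataset-class].
#' @export
joinResponse <- function(block, composition) {
  stopifnot(is(block, "SpectraBlock"))
  if (nrow(block@absorbance) == 0L) stop("empty spectra block")
  ids <- as.character(composition$sample_id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate sample_id in composition table: ", paste(dup, collapse = ", "))
  }
  hit <- match(block@sampleIds, ids)
  if (any(is.na(hit))) {
    stop("sample_id missing from composition table: ",
         paste(unique(block@sampleIds[is.na(hit)]), collapse = ", "))
  }
  conc <- computeConcentration(
    composition$mass_starch, composition$mass_lactose,
    composition$mass_mix_a, composition$mass_mix_b,
    composition$conc_stock_a, composition$conc_stock_b, round = FALSE
  )
  meta <- composition[hit, , drop = FALSE]
  rownames(meta) <- NULL
  nirDataset(block, response = conc[hit], metadata = meta)
}
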
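# Spectrum container and file formats.

#' Spectrum set container
#'
#' A `spectrum_set` holds one or more absorbance spectra that share a single
#' wavenumber grid, together with a metadata table keyed by sample id.  The
#' grid is stored ascending; descending input is re-ordered (with the
#' absorbance rows permuted accordingly).
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1, strictly
#'   monotone.
#' @param absorbance Numeric matrix with one row per grid point and one
#'   column per sample (a plain vector is treated as a single sample).
#'   Column names are the sample ids and must be unique.
#' @param metadata Optional `data.frame` with a `sample_id` column matching
#'   the absorbance columns; defaults to a bare id table.
#'
#' @return An object of class `spectrum_set`: a list with elements
#'   `wavenumbers`, `absorbance` and `metadata`.
#' @export
spectrum_set <- function(wavenumbers, absorbance, metadata = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) == 0) {
    ps_error("wavenumber grid is empty", "phospec_empty_grid")
  }
  if (is.null(dim(absorbance))) {
    absorbance <- matrix(as.numeric(absorbance), ncol = 1)
  }
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (nrow(absorbance) != length(wavenumbers)) {
    ps_error(
      sprintf(
        "absorbance has %d rows but the grid has %d points",
        nrow(absorbance), length(wavenumbers)
      ),
      "phospec_length_mismatch"
    )
  }
  if (length(wavenumbers) > 1) {
    dw <- diff(wavenumbers)
    if (any(dw == 0) || (any(dw > 0) && any(dw < 0))) {
      ps_error(
        "wavenumber grid must be strictly monotone",
        "phospec_grid_error"
      )
    }
    if (all(dw < 0)) {
      wavenumbers <- rev(wavenumbers)
      absorbance <- absorbance[rev(seq_len(nrow(absorbance))), , drop = FALSE]
    }
  }
  if (!all(is.finite(absorbance))) {
    ps_error("absorbance values must all be finite", "phospec_nonfinite")
  }
  if (is.null(colnames(absorbance))) {
    colnames(absorbance) <- sprintf("s%03d", seq_len(ncol(absorbance)))
  }
  ids <- colnames(absorbance)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    ps_error(
      sprintf("duplicated sample_id: %s", paste(dup, collapse = ", ")),
      "phospec_duplicate_id"
    )
  }
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  }
  if (!"sample_id" %in% names(metadata)) {
    ps_error("metadata must contain a sample_id column", "phospec_metadata_error")
  }
  if (!setequal(metadata$sample_id, ids) || nrow(metadata) != length(ids)) {
    ps_error(
      "metadata sample_id set does not match the absorbance columns",
      "phospec_metadata_error"
    )
  }
  metadata <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance, metadata = metadata),
    class = "spectrum_set"
  )
}

#' Number of spectra in a set
#' @param x A `spectrum_set`.
#' @return Integer count of samples.
#' @export
n_spectra <- function(x) {
  stopifnot(inherits(x, "spectrum_set"))
  ncol(x$absorbance)
}

#' @export
#' @method print spectrum_set
print.spectrum_set <- function(x, ...) {
  w <- x$wavenumbers
  cat(sprintf(
    "<spectrum_set> %d spectra, %d points, %.0f-%.0f cm^-1\n",
    ncol(x$absorbance), length(w), min(w), max(w)
  ))
  cat("metadata columns:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @method [ spectrum_set
`[.spectrum_set` <- function(x, i) {
  if (is.character(i)) i <- match(i, colnames(x$absorbance))
  spectrum_set(
    x$wavenumbers,
    x$absorbance[, i, drop = FALSE],
    x$metadata[i, , drop = FALSE]
  )
}

#' Read spectra from file
#'
#' Supported formats: `"wide-csv"` (first column `wavenumber`, one column per
#' sample) and `"jcamp-like"`, a plain-text dialect of JCAMP-DX restricted to
#' uncompressed `x y` pairs (one labelled block per sample, terminated by
#' `##END=`).
#'
#' @param path Path to the spectra file.
#' @param format One of `"wide-csv"`, `"jcamp-like"`.
#' @param metadata_path Optional path to a delimited metadata table with a
#'   `sample_id` column.
#' @return A [spectrum_set].
#' @export
read_spectra <- function(path, format = c("wide-csv", "jcamp-like"),
                         metadata_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    ps_error(sprintf("file not found: %s", path), "phospec_io_error")
  }
  if (format == "wide-csv") {
    # read.table uniquifies duplicated header names, so check the raw header
    header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
    if (anyDuplicated(header)) {
      dup <- unique(header[duplicated(header)])
      ps_error(
        sprintf("%s: duplicated sample_id: %s", path,
                paste(dup, collapse = ", ")),
        "phospec_duplicate_id"
      )
    }
    tab <- utils::read.csv(path, check.names = FALSE)
    if (ncol(tab) < 2) {
      ps_error(sprintf("%s: need a wavenumber column plus >= 1 sample", path),
               "phospec_parse_error")
    }
    if (names(tab)[1] != "wavenumber") {
      ps_error(sprintf("%s: first column must be named 'wavenumber'", path),
               "phospec_parse_error")
    }
    if (anyNA(tab)) {
      bad <- names(tab)[colSums(is.na(tab)) > 0]
      ps_error(
        sprintf("%s: missing values in column(s) %s", path,
                paste(bad, collapse = ", ")),
        "phospec_parse_error"
      )
    }
    abs_mat <- as.matrix(tab[, -1, drop = FALSE])
    set <- spectrum_set(tab[[1]], abs_mat)
  } else {
    set <- read_jcamp_like(path)
  }
  if (!is.null(metadata_path)) {
    meta <- utils::read.csv(metadata_path, check.names = FALSE)
    set <- spectrum_set(set$wavenumbers, set$absorbance, meta)
  }
  set
}

read_jcamp_like <- function(path) {
  lines <- readLines(path)
  ids <- character(0)
  blocks <- list()
  cur_id <- NULL
  cur <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") next
    if (startsWith(ln, "##TITLE=")) {
      cur_id <- sub("^##TITLE=", "", ln)
      cur <- character(0)
    } else if (startsWith(ln, "##END")) {
      if (is.null(cur_id)) {
        ps_error(sprintf("%s: ##END= without ##TITLE=", path),
                 "phospec_parse_error")
      }
      ids <- c(ids, cur_id)
      blocks <- c(blocks, list(cur))
      cur_id <- NULL
      cur <- NULL
    } else if (startsWith(ln, "##")) {
      next  # other labelled-data records are carried but not interpreted
    } else if (!is.null(cur_id)) {
      cur <- c(cur, ln)
    }
  }
  if (length(ids) == 0) {
    ps_error(sprintf("%s: no spectrum blocks found", path), "phospec_parse_error")
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    ps_error(sprintf("%s: duplicated sample_id: %s", path,
                     paste(dup, collapse = ", ")),
             "phospec_duplicate_id")
  }
  parse_block <- function(txt, id) {
    con <- textConnection(txt)
    on.exit(close(con))
    xy <- tryCatch(
      utils::read.table(con, col.names = c("x", "y")),
      error = function(e) {
        ps_error(sprintf("%s: malformed data in block '%s'", path, id),
                 "phospec_parse_error")
      }
    )
    xy
  }
  xys <- Map(parse_block, blocks, ids)
  grid <- xys[[1]]$x
  npts <- vapply(xys, nrow, integer(1))
  if (any(npts != length(grid))) {
    ps_error(
      sprintf("%s: blocks have differing point counts (%s)", path,
              paste(ids[npts != length(grid)], collapse = ", ")),
      "phospec_parse_error"
    )
  }
  for (i in seq_along(xys)) {
    if (any(xys[[i]]$x != grid)) {
      ps_error(sprintf("%s: block '%s' is not on the shared grid", path, ids[i]),
               "phospec_parse_error")
    }
  }
  abs_mat <- vapply(xys, function(b) b$y, numeric(length(grid)))
  abs_mat <- matrix(abs_mat, ncol = length(ids),
                    dimnames = list(NULL, ids))
  spectrum_set(grid, abs_mat)
}

#' Write spectra to file
#'
#' Writes the set in a form [read_spectra] reads back losslessly (values are
#' serialized at full double precision).  Metadata is written alongside as a
#' separate CSV when `metadata_path` is given.
#'
#' @param set A non-empty [spectrum_set].
#' @inheritParams read_spectra
#' @return Invisibly, `path`.
#' @export
write_spectra <- function(set, path, format = c("wide-csv", "jcamp-like"),
                          metadata_path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(set, "spectrum_set"))
  if (ncol(set$absorbance) == 0) {
    ps_error("refusing to write an empty spectrum_set", "phospec_empty_set")
  }
  fmt <- function(v) formatC(v, format = "g", digits = 17)
  if (format == "wide-csv") {
    tab <- data.frame(wavenumber = fmt(set$wavenumbers), check.names = FALSE)
    for (id in colnames(set$absorbance)) {
      tab[[id]] <- fmt(set$absorbance[, id])
    }
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (id in colnames(set$absorbance)) {
      writeLines(c(
        sprintf("##TITLE=%s", id),
        "##JCAMP-DX=4.24",
        "##DATA TYPE=INFRARED SPECTRUM",
        "##XUNITS=1/CM",
        "##YUNITS=ABSORBANCE",
        sprintf("##NPOINTS=%d", length(set$wavenumbers)),
        "##XYDATA=(XY..XY)"
      ), con)
      writeLines(paste(fmt(set$wavenumbers), fmt(set$absorbance[, id])), con)
      writeLines("##END=", con)
    }
  }
  if (!is.null(metadata_path)) {
    utils::write.csv(set$metadata, metadata_path, row.names = FALSE)
  }
  invisible(path)
}

#' Restrict a spectrum set to a wavenumber region
#'
#' Keeps grid points `p` with `lo <= p < hi` (half-open convention, so
#' adjacent regions tile without double-counting boundary points).
#'
#' @param set A [spectrum_set].
#' @param lo,hi Region bounds in cm^-1, `lo < hi`.
#' @return A [spectrum_set] on the restricted grid.
#' @export
restrict_region <- function(set, lo, hi) {
  stopifnot(inherits(set, "spectrum_set"), lo < hi)
  keep <- set$wavenumbers >= lo & set$wavenumbers < hi
  if (!any(keep)) {
    ps_error(
      sprintf("region [%g, %g) does not overlap the grid (%g-%g)",
              lo, hi, min(set$wavenumbers), max(set$wavenumbers)),
      "phospec_empty_region"
    )
  }
  spectrum_set(
    set$wavenumbers[keep],
    set$absorbance[keep, , drop = FALSE],
    set$metadata
  )
}

#' Resample a spectrum set onto a new grid
#'
#' Linear interpolation onto `grid`.  This is the explicit alternative to the
#' hard grid-compatibility error raised by [predict_available]: resampling is
#' never done silently.
#'
#' @param set A [spectrum_set].
#' @param grid Target wavenumber grid, within the range of the current grid.
#' @return A [spectrum_set] on `grid`.
#' @export
resample_to_grid <- function(set, grid) {
  stopifnot(inherits(set, "spectrum_set"))
  grid <- as.numeric(grid)
  if (min(grid) < min(set$wavenumbers) || max(grid) > max(set$wavenumbers)) {
    ps_error("target grid extends beyond the measured range",
             "phospec_grid_error")
  }
  abs_mat <- apply(set$absorbance, 2, function(y) {
    stats::approx(set$wavenumbers, y, xout = grid)$y
  })
  abs_mat <- matrix(abs_mat, ncol = ncol(set$absorbance),
                    dimnames = list(NULL, colnames(set$absorbance)))
  spectrum_set(grid, abs_mat, set$metadata)
}
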
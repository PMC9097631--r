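#' EPR dataset container for file I/O
#'
#' A thin format-neutral wrapper: one or two linear coordinate axes with
#' unit strings, a real or complex value array, and the raw descriptor
#' key/value map when the data came from a BES3T pair.
#'
#' @param axes List of one or two axes, each a list with elements `values`
#'   (numeric vector), `unit` (string) and optionally `name`.
#' @param values Numeric or complex vector (1D) or matrix (2D,
#'   `length(axes[[1]]$values)` rows).
#' @param params Named character map of descriptor lines (may be empty).
#' @return Object of class `epr_dataset`.
#' @export
epr_dataset <- function(axes, values, params = character()) {
  if (!is.list(axes) || !length(axes) %in% 1:2) {
    stop("axes must be a list of 1 or 2 axes", call. = FALSE)
  }
  for (ax in axes) {
    if (is.null(ax$values) || is.null(ax$unit)) {
      stop("each axis needs 'values' and 'unit'", call. = FALSE)
    }
  }
  if (length(axes) == 1L) {
    values <- as.vector(values)
    if (length(values) != length(axes[[1]]$values)) {
      stop("values length must match the axis", call. = FALSE)
    }
  } else {
    values <- as.matrix(values)
    if (nrow(values) != length(axes[[1]]$values) ||
        ncol(values) != length(axes[[2]]$values)) {
      stop("values shape must match the axes", call. = FALSE)
    }
  }
  structure(list(axes = axes, values = values, params = params),
            class = "epr_dataset")
}

#' @export
print.epr_dataset <- function(x, ...) {
  dims <- vapply(x$axes, function(a) length(a$values), integer(1))
  cat(sprintf("epr_dataset: %s points (%s)%s\n",
              paste(dims, collapse = " x "),
              paste(vapply(x$axes, `[[`, "", "unit"), collapse = ", "),
              if (is.complex(x$values)) ", complex" else ""))
  invisible(x)
}

.dsc_parse <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^[*#]", lines)]
  keys <- sub("^(\\S+).*$", "\\1", lines)
  vals <- trimws(sub("^\\S+\\s*", "", lines))
  vals <- gsub("^'|'$", "", vals)
  stats::setNames(vals, keys)
}

.dsc_num <- function(p, key) {
  if (!key %in% names(p)) stop("descriptor lacks required key ", key, call. = FALSE)
  as.numeric(p[[key]])
}

.dsc_get <- function(p, key, default = NA_character_) {
  if (key %in% names(p)) p[[key]] else default
}

.axis_from_dsc <- function(p, prefix) {
  n <- .dsc_num(p, paste0(prefix, "PTS"))
  mn <- .dsc_num(p, paste0(prefix, "MIN"))
  wid <- .dsc_num(p, paste0(prefix, "WID"))
  unit <- if (paste0(prefix, "UNI") %in% names(p)) p[[paste0(prefix, "UNI")]] else ""
  vals <- mn + (seq_len(n) - 1) * wid / (n - 1)
  if (identical(unit, "G")) {      # normalize Gauss to mT
    vals <- vals / 10
    unit <- "mT"
  }
  name <- if (paste0(prefix, "NAM") %in% names(p)) p[[paste0(prefix, "NAM")]] else prefix
  list(values = vals, unit = unit, name = name)
}

#' Read a Bruker BES3T dataset
#'
#' Parses the text descriptor (`.DSC`) and decodes the companion binary
#' (`.DTA`). Supported subset: IKKF REAL/CPLX, IRFMT D (float64) and
#' I (int32), BSEQ BIG/LIT, linear X and optionally Y axes (XTYP/YTYP IDX).
#' Nonlinear companion axis files (.XGF/.YGF, XTYP IGD) are detected and
#' rejected. Gauss field axes are normalized to mT.
#'
#' @param dsc_path Path to the `.DSC` file; the `.DTA` must sit alongside.
#' @return An [epr_dataset].
#' @export
read_bes3t <- function(dsc_path) {
  if (!file.exists(dsc_path)) stop("no such file: ", dsc_path, call. = FALSE)
  dta_path <- sub("\\.DSC$", ".DTA", dsc_path, ignore.case = TRUE)
  if (identical(dta_path, dsc_path)) dta_path <- paste0(dsc_path, ".DTA")
  if (!file.exists(dta_path)) {
    stop("missing companion data file: ", dta_path, call. = FALSE)
  }
  p <- .dsc_parse(readLines(dsc_path, warn = FALSE))
  for (prefix in c("X", "Y")) {
    if (identical(.dsc_get(p, paste0(prefix, "TYP")), "IGD")) {
      stop("nonlinear ", prefix, " axis (companion .", prefix,
           "GF file) is not supported", call. = FALSE)
    }
  }
  irfmt <- .dsc_get(p, "IRFMT", "D")
  if (!irfmt %in% c("D", "I")) {
    stop("unsupported IRFMT code '", irfmt, "' (supported: D, I)", call. = FALSE)
  }
  endian <- if (identical(.dsc_get(p, "BSEQ"), "LIT")) "little" else "big"
  complex <- identical(.dsc_get(p, "IKKF"), "CPLX")
  ax1 <- .axis_from_dsc(p, "X")
  two_d <- "YPTS" %in% names(p) && .dsc_num(p, "YPTS") > 1
  axes <- list(ax1)
  if (two_d) axes <- c(axes, list(.axis_from_dsc(p, "Y")))
  npts <- prod(vapply(axes, function(a) length(a$values), numeric(1)))
  nvals <- npts * (1L + complex)
  size <- if (irfmt == "D") 8L else 4L
  fsize <- file.info(dta_path)$size
  if (fsize != nvals * size) {
    stop("data size mismatch: descriptor implies ", nvals * size,
         " bytes, file has ", fsize, call. = FALSE)
  }
  con <- file(dta_path, "rb")
  on.exit(close(con))
  raw_vals <- if (irfmt == "D") {
    readBin(con, "double", n = nvals, size = 8L, endian = endian)
  } else {
    as.numeric(readBin(con, "integer", n = nvals, size = 4L, endian = endian))
  }
  vals <- if (complex) {
    complex(real = raw_vals[c(TRUE, FALSE)], imaginary = raw_vals[c(FALSE, TRUE)])
  } else {
    raw_vals
  }
  # X varies fastest on disk; in-memory layout is axis1 = rows
  if (two_d) vals <- matrix(vals, nrow = length(ax1$values))
  epr_dataset(axes, vals, params = p)
}

#' Write a Bruker BES3T dataset
#'
#' Emits a minimal conformant `.DSC`/`.DTA` pair re-readable by
#' [read_bes3t()], preserving float64 values bit-exactly. Complex values
#' are stored interleaved (IKKF CPLX).
#'
#' @param ds An [epr_dataset].
#' @param path Output path; a `.DSC`/`.DTA` extension is stripped and both
#'   files are written.
#' @param endian `"big"` (default, BSEQ BIG) or `"little"`.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_bes3t <- function(ds, path, endian = c("big", "little")) {
  endian <- match.arg(endian)
  stopifnot(inherits(ds, "epr_dataset"))
  base <- sub("\\.(DSC|DTA)$", "", path, ignore.case = TRUE)
  complex <- is.complex(ds$values)
  two_d <- length(ds$axes) == 2L
  ax_block <- function(ax, prefix) {
    v <- ax$values
    c(sprintf("%sTYP\tIDX", prefix),
      sprintf("%sPTS\t%d", prefix, length(v)),
      sprintf("%sMIN\t%.17g", prefix, v[1]),
      sprintf("%sWID\t%.17g", prefix, v[length(v)] - v[1]),
      sprintf("%sUNI\t'%s'", prefix, ax$unit),
      sprintf("%sNAM\t'%s'", prefix, if (is.null(ax$name)) prefix else ax$name))
  }
  lines <- c(
    "#DESC\t1.2 * DESCRIPTOR INFORMATION ***********************",
    "DSRC\tEXP",
    sprintf("BSEQ\t%s", if (endian == "big") "BIG" else "LIT"),
    sprintf("IKKF\t%s", if (complex) "CPLX" else "REAL"),
    "IRFMT\tD",
    if (complex) "IIFMT\tD" else NULL,
    ax_block(ds$axes[[1]], "X"),
    if (two_d) ax_block(ds$axes[[2]], "Y") else NULL
  )
  extra <- ds$params[setdiff(names(ds$params), c("BSEQ", "IKKF", "IRFMT", "IIFMT",
    "XTYP", "XPTS", "XMIN", "XWID", "XUNI", "XNAM",
    "YTYP", "YPTS", "YMIN", "YWID", "YUNI", "YNAM", "DSRC"))]
  if (length(extra)) lines <- c(lines, paste0(names(extra), "\t", extra))
  dsc <- paste0(base, ".DSC")
  dta <- paste0(base, ".DTA")
  writeLines(lines, dsc)
  v <- if (two_d) as.vector(ds$values) else ds$values  # axis1 fastest
  out <- if (complex) as.vector(rbind(Re(v), Im(v))) else as.numeric(v)
  con <- file(dta, "wb")
  on.exit(close(con))
  writeBin(out, con, size = 8L, endian = endian)
  invisible(c(dsc, dta))
}

#' Read a plain ASCII spectrum or map
#'
#' Two layouts are accepted: a two-column table (axis, value) for 1D data,
#' and a matrix with two axis header lines (`# axis1: <name_unit> v1 v2
#' ...`, `# axis2: ...`) for 2D data, as written by [write_ascii()]. Other
#' `#` comment lines are skipped.
#'
#' @param path File path.
#' @return An [epr_dataset].
#' @export
read_ascii <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ax_hdr <- grepl("^#\\s*axis[12]:", lines)
  data_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (!length(data_idx)) stop("no data rows in ", path, call. = FALSE)
  toks <- strsplit(trimws(lines[data_idx]), "\\s+")
  nfield <- lengths(toks)
  if (length(unique(nfield)) != 1L) {
    bad <- data_idx[which(nfield != nfield[1])[1]]
    stop("ragged row at line ", bad, " of ", path, call. = FALSE)
  }
  parse_axis_hdr <- function(which) {
    ln <- lines[ax_hdr][grepl(paste0("axis", which, ":"), lines[ax_hdr])][1]
    body <- sub(paste0("^#\\s*axis", which, ":\\s*"), "", ln)
    parts <- strsplit(trimws(body), "\\s+")[[1]]
    list(values = as.numeric(parts[-1]), unit = sub("^.*_", "", parts[1]),
         name = parts[1])
  }
  if (any(ax_hdr)) {
    ax1 <- parse_axis_hdr(1)
    ax2 <- parse_axis_hdr(2)
    m <- do.call(rbind, lapply(toks, as.numeric))
    if (nrow(m) != length(ax1$values) || ncol(m) != length(ax2$values)) {
      stop("matrix shape does not match axis headers in ", path, call. = FALSE)
    }
    return(epr_dataset(list(ax1, ax2), m))
  }
  if (nfield[1] < 2L) {
    stop("expected two columns (axis, value) in ", path, call. = FALSE)
  }
  m <- do.call(rbind, lapply(toks, as.numeric))
  if (any(is.na(m))) stop("non-numeric data in ", path, call. = FALSE)
  epr_dataset(list(list(values = m[, 1], unit = "", name = "x")), m[, 2])
}

#' Write a dataset as plain ASCII
#'
#' 1D data become a two-column table; 2D data a matrix preceded by two
#' axis header lines understood by [read_ascii()]. Complex values are not
#' representable in this layout.
#'
#' @param ds An [epr_dataset] with real values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii <- function(ds, path) {
  stopifnot(inherits(ds, "epr_dataset"))
  if (is.complex(ds$values)) {
    stop("complex data cannot be written as ASCII; use write_bes3t()", call. = FALSE)
  }
  if (length(ds$axes) == 1L) {
    lines <- c(sprintf("# %s (%s)  intensity",
                       ds$axes[[1]]$name %||% "x", ds$axes[[1]]$unit),
               sprintf("%.17g %.17g", ds$axes[[1]]$values, ds$values))
  } else {
    hdr <- function(ax, which) {
      nm <- gsub("\\s+", "", paste0(ax$name %||% paste0("axis", which), "_", ax$unit))
      sprintf("# axis%d: %s %s", which, nm,
              paste(sprintf("%.17g", ax$values), collapse = " "))
    }
    lines <- c(hdr(ds$axes[[1]], 1L), hdr(ds$axes[[2]], 2L),
               apply(ds$values, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
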
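#' Read a contig spectrum from a plain-text file
#'
#' Two dialects are accepted. Dense: one count per line, the line number
#' being the contig size `q`. Sparse: two whitespace-separated columns
#' `q count`; omitted `q` values are zero. Comment lines of the form
#' `#key=value` may carry the sequencing metadata (`R`, `r`, `o`);
#' values passed as function arguments override the header (with a
#' warning on conflict). Counts must parse as non-negative numbers.
#'
#' @param path file path.
#' @param R,r,o optional sequencing metadata overriding any header values.
#' @return A [contig_spectrum()].
#' @export
read_contig_spectrum <- function(path, R = NULL, r = NULL, o = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  is_comment <- grepl("^\\s*#", lines)
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*=\\s*([0-9.eE+-]+)",
                                cl))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- as.numeric(m[3])
  }
  body <- trimws(lines[!is_comment])
  body <- body[nzchar(body)]
  if (length(body) == 0L) stop("spectrum file has no data lines: ", path,
                               call. = FALSE)
  fields <- strsplit(body, "\\s+")
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1L || !(ncol %in% c(1L, 2L)))
    stop("mixed or unrecognised spectrum format in ", path, call. = FALSE)
  parse_num <- function(x, line_no) {
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v)) || any(v < 0))
      stop("invalid count on line ", line_no, " of ", path, call. = FALSE)
    v
  }
  line_nos <- which(!is_comment)[seq_along(body)]
  if (ncol == 1L) {
    C <- vapply(seq_along(fields), function(k)
      parse_num(fields[[k]][1], line_nos[k]), numeric(1))
  } else {
    q <- vapply(seq_along(fields), function(k)
      parse_num(fields[[k]][1], line_nos[k]), numeric(1))
    cnt <- vapply(seq_along(fields), function(k)
      parse_num(fields[[k]][2], line_nos[k]), numeric(1))
    if (any(q < 1) || any(q != round(q)))
      stop("sparse dialect requires integer q >= 1 in ", path, call. = FALSE)
    C <- numeric(max(q))
    C[q] <- cnt
  }
  pick <- function(flag, key, default = NULL) {
    if (!is.null(flag)) {
      if (!is.null(meta[[key]]) && meta[[key]] != flag)
        warning("header ", key, "=", meta[[key]], " overridden by argument ",
                flag, call. = FALSE)
      return(flag)
    }
    if (!is.null(meta[[key]])) return(meta[[key]])
    default
  }
  R <- pick(R, "R")
  if (is.null(R))
    stop("total read count R missing: supply it as an argument or a ",
         "'#R=' header", call. = FALSE)
  contig_spectrum(C, R = R, r = pick(r, "r", 100), o = pick(o, "o", 35))
}

#' Write a contig spectrum to a plain-text file
#'
#' Writes the dense (default) or sparse dialect of
#' [read_contig_spectrum()], with a `#key=value` header carrying `R`, `r`
#' and `o` so the file is self-describing.
#'
#' @param obs a [contig_spectrum()].
#' @param path output path.
#' @param sparse write the two-column `q count` dialect, omitting empty
#'   bins.
#' @param header write the metadata header.
#' @export
write_contig_spectrum <- function(obs, path, sparse = FALSE, header = TRUE) {
  stopifnot(inherits(obs, "contig_spectrum"))
  out <- character(0)
  if (header)
    out <- c(sprintf("#R=%d", obs$seq$R), sprintf("#r=%d", obs$seq$r),
             sprintf("#o=%d", obs$seq$o))
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)
  if (sparse) {
    nz <- which(obs$C > 0)
    out <- c(out, paste(nz, fmt(obs$C[nz])))
  } else {
    out <- c(out, fmt(obs$C))
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a fit result to JSON (and optionally a one-line TSV summary)
#'
#' The JSON result embeds the estimates, residual, derived evenness and
#' dominant abundance, the full search bounds, the seed and the package
#' version, so every output is reproducible from its own metadata. The
#' optional TSV line carries the headline `L`, `M` and evenness columns.
#'
#' @param fit a `"virome_fit"`.
#' @param path output JSON path.
#' @param tsv optional path for the one-line TSV summary.
#' @return `path`, invisibly.
#' @export
write_result <- function(fit, path, tsv = NULL) {
  stopifnot(inherits(fit, "virome_fit"))
  spec <- fit$spec
  out <- list(
    M = fit$M, L = fit$L, T = fit$T, d = fit$d,
    S_min = fit$S_min, evenness = fit$evenness, f_max = fit$f_max,
    q_max = fit$q_max, fixed_L = fit$fixed_L,
    seq = unclass(fit$obs$seq),
    bounds = list(M = spec$M_bounds, L = spec$L_bounds, d = spec$d_bounds),
    N_L = spec$N_L, distributions = spec$distributions,
    seed = fit$seed,
    version = as.character(utils::packageVersion("virospectra")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(tsv)) {
    df <- data.frame(L = fit$L, M = fit$M, evenness = fit$evenness)
    utils::write.table(df, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON fit result
#'
#' @param path JSON file written by [write_result()].
#' @return A list of the stored fields.
#' @export
read_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
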
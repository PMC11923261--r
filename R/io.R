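#' Write or read a point cloud as CSV
#'
#' Plain CSV with columns `x`, `y`, `z` and a commented metadata header
#' (`# key: value` lines) carrying the scenario tag, the confinement
#' parameters, the seed and the source, so that a written cloud reads back
#' equal (coordinates preserved to better than 1e-9 nm).
#'
#' @param cloud A `point_cloud` (see [sample_free_end()]).
#' @param path File path.
#' @return `read_point_cloud()` returns a `point_cloud`;
#'   `write_point_cloud()` returns `path` invisibly.
#' @export
write_point_cloud <- function(cloud, path) {
  pts <- as_xyz(cloud)
  params <- attr(cloud, "params")
  hdr <- c(paste0("# scenario: ", attr(cloud, "scenario") %||% "unknown"),
           paste0("# source: ", attr(cloud, "source") %||% "unknown"),
           paste0("# seed: ", attr(cloud, "seed") %||% NA))
  if (!is.null(params)) {
    keep <- names(params)[!vapply(params, is.null, logical(1))]
    hdr <- c(hdr, vapply(keep, function(nm)
      paste0("# ", nm, ": ", format(params[[nm]], digits = 17)), character(1)))
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  writeLines("x,y,z", con)
  writeLines(paste(format(pts$x, digits = 17, trim = TRUE, scientific = FALSE),
                   format(pts$y, digits = 17, trim = TRUE, scientific = FALSE),
                   format(pts$z, digits = 17, trim = TRUE, scientific = FALSE),
                   sep = ","), con)
  invisible(path)
}

#' @rdname write_point_cloud
#' @export
read_point_cloud <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  meta <- parse_kv_header(lines[is_hdr])
  body <- lines[!is_hdr]
  if (length(body) < 1 || !grepl("^\\s*x\\s*,\\s*y\\s*,\\s*z", body[1]))
    abort("malformed point-cloud file: missing x,y,z column line")
  data_lines <- body[-1]
  if (!length(data_lines)) abort("empty point cloud: file has a header but no points")
  line_no <- which(!is_hdr)[-1]            # file line numbers of data rows
  fields <- strsplit(data_lines, ",", fixed = TRUE)
  bad_len <- which(lengths(fields) != 3)
  if (length(bad_len))
    abort(sprintf("malformed point-cloud row at line %d: expected 3 fields, got %d",
                  line_no[bad_len[1]], lengths(fields)[bad_len[1]]))
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 3,
              byrow = TRUE)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad))
    abort(sprintf("non-finite coordinate at line %d, field %s",
                  line_no[bad[1, 1]], c("x", "y", "z")[bad[1, 2]]))
  params <- NULL
  par_keys <- intersect(names(meta), c("beta_k", "L", "beta_k_prime", "z_max",
                                       "beta_k_dprime", "h_max", "n_terms"))
  if (length(par_keys))
    params <- do.call(confinement_params, lapply(meta[par_keys], as.numeric))
  seed <- suppressWarnings(as.integer(meta$seed))
  structure(tibble(x = m[, 1], y = m[, 2], z = m[, 3]),
            class = c("point_cloud", class(tibble())),
            scenario = meta$scenario, params = params,
            seed = if (length(seed) && !is.na(seed)) seed else NULL,
            source = meta$source %||% "file")
}

#' Read free-end positions from an oxDNA configuration/topology pair
#'
#' Minimal reader for the standard oxDNA text layout: the topology's first
#' line gives the nucleotide and strand counts; each configuration frame is
#' three header lines (`t = ...`, `b = ...`, `E = ...`) followed by one
#' line per nucleotide whose first three fields are the center-of-mass
#' position in simulation units. The indexed nucleotide's position series
#' is extracted, converted to nm (0.8518 nm per oxDNA length unit, the
#' standard convention for the format) and translated frame-by-frame so
#' that the tether nucleotide sits at the origin.
#'
#' @param conf_path Path to the configuration/trajectory file.
#' @param topology_path Path to the topology file.
#' @param nucleotide_index 1-based index of the tracked (free-end)
#'   nucleotide.
#' @param tether_index 1-based index of the tether nucleotide used as
#'   origin (default 1).
#' @return A `point_cloud` (one row per frame, `source =
#'   "trajectory-file"`).
#' @export
read_oxdna_positions <- function(conf_path, topology_path, nucleotide_index,
                                 tether_index = 1L) {
  for (f in c(conf_path, topology_path))
    if (!file.exists(f)) abort(paste0("file not found: ", f))
  top1 <- strsplit(trimws(readLines(topology_path, n = 1L)), "\\s+")[[1]]
  n_nt <- suppressWarnings(as.integer(top1[1]))
  if (is.na(n_nt) || n_nt < 1)
    abort("malformed topology: first line must start with the nucleotide count")
  for (idx in c(nucleotide_index, tether_index))
    if (!is.numeric(idx) || length(idx) != 1L || idx < 1 || idx > n_nt)
      abort(sprintf("nucleotide index %s out of range [1, %d]",
                    format(idx), n_nt))
  lines <- readLines(conf_path)
  frame_len <- 3L + n_nt
  if (length(lines) %% frame_len != 0)
    abort(sprintf("malformed configuration file: %d lines is not a multiple of %d (3 header + %d nucleotide lines per frame)",
                  length(lines), frame_len, n_nt))
  n_frames <- length(lines) %/% frame_len
  oxdna_nm <- 0.8518
  pos <- matrix(NA_real_, n_frames, 3)
  for (fr in seq_len(n_frames)) {
    off <- (fr - 1L) * frame_len
    hdr <- lines[off + 1:3]
    if (!grepl("^\\s*t\\s*=", hdr[1]) || !grepl("^\\s*b\\s*=", hdr[2]) ||
        !grepl("^\\s*E\\s*=", hdr[3]))
      abort(sprintf("malformed timestep header in frame %d", fr))
    get_xyz <- function(i) {
      f <- suppressWarnings(as.numeric(
        strsplit(trimws(lines[off + 3L + i]), "\\s+")[[1]][1:3]))
      if (any(!is.finite(f)))
        abort(sprintf("malformed nucleotide line in frame %d (nucleotide %d)",
                      fr, i))
      f
    }
    pos[fr, ] <- (get_xyz(nucleotide_index) - get_xyz(tether_index)) * oxdna_nm
  }
  structure(tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3]),
            class = c("point_cloud", class(tibble())),
            scenario = NULL, params = NULL, seed = NULL,
            source = "trajectory-file")
}
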
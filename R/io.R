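#' Streamline dataset I/O
#'
#' The BrainVISA bundles format stores a whole dataset in one binary
#' payload file (`*.bundlesdata`) and a small text header (`*.bundles`).
#' The header is a Python-literal attribute dictionary whose `'bundles'`
#' entry lists alternating bundle names and first-fiber indexes; the
#' payload is, per fiber, a little-endian int32 point count followed by
#' that many little-endian float32 (x, y, z) triplets in mm.
#'
#' Ground-truth metadata (per-bundle parameters, per-fiber labels, crossing
#' pairs) travels in a companion JSON manifest.
#'
#' @name bundles-io
NULL

bundles_paths <- function(path) {
  base <- sub("\\.bundles(data)?$", "", path)
  list(header = paste0(base, ".bundles"),
       data = paste0(base, ".bundlesdata"))
}

#' Write bundles to a BrainVISA bundles/bundlesdata file pair
#'
#' Coordinates are stored as little-endian single precision; two writes of
#' the same input produce byte-identical files.
#'
#' @param x A `fibersim_dataset`, a list of [bundle()]s, or a single
#'   bundle.
#' @param path Output path; the `.bundles`/`.bundlesdata` extensions are
#'   added to (or normalized on) the given path.
#' @return Invisibly, the two file paths.
#' @export
write_bundles <- function(x, path) {
  if (inherits(x, "fibersim_dataset")) x <- x$bundles
  if (inherits(x, "fibersim_bundle")) x <- list(x)
  stopifnot(length(x) > 0L || is.list(x))
  p <- bundles_paths(path)
  offsets <- integer(length(x))
  total <- 0L
  for (i in seq_along(x)) {
    offsets[i] <- total
    total <- total + n_fibers(x[[i]])
  }
  entries <- vapply(seq_along(x), function(i) {
    sprintf("'%s', %d", x[[i]]$label, offsets[i])
  }, character(1L))
  header <- paste0(
    "attributes = {\n",
    "    'binary' : 1,\n",
    "    'bundles' : [ ", paste(entries, collapse = ", "), " ],\n",
    "    'byte_order' : 'DCBA',\n",
    "    'curves_count' : ", total, ",\n",
    "    'data_file_name' : '*.bundlesdata',\n",
    "    'format' : 'bundles_1.0',\n",
    "    'space_dimension' : 3\n",
    "  }\n")
  writeLines(header, p$header, sep = "")
  con <- file(p$data, "wb")
  on.exit(close(con))
  for (b in x) {
    for (f in b$fibers) {
      writeBin(nrow(f), con, size = 4L, endian = "little")
      writeBin(as.numeric(t(f)), con, size = 4L, endian = "little")
    }
  }
  invisible(unlist(p))
}

#' Read a BrainVISA bundles/bundlesdata file pair
#'
#' @param path Path to either file of the pair.
#' @return A list: `bundles` (list of [bundle()]s, fibers grouped by the
#'   header's name/offset pairs) and `labels` (per-fiber bundle label,
#'   character, in file order).
#' @export
read_bundles <- function(path) {
  p <- bundles_paths(path)
  if (!file.exists(p$header))
    stop("missing header file: ", p$header)
  if (!file.exists(p$data))
    stop("missing data file: ", p$data)
  header <- paste(readLines(p$header, warn = FALSE), collapse = "\n")
  bm <- regmatches(header,
                   regexpr("'bundles'\\s*:\\s*\\[[^]]*\\]", header))
  if (length(bm) == 0L) stop("header has no 'bundles' attribute")
  inner <- sub("^'bundles'\\s*:\\s*\\[", "", sub("\\]$", "", bm))
  toks <- regmatches(inner, gregexpr("'[^']*'|-?[0-9]+", inner))[[1L]]
  if (length(toks) %% 2L != 0L)
    stop("malformed 'bundles' attribute: expected name/offset pairs")
  if (length(toks) == 0L) {
    names_ <- character(0L); offsets <- integer(0L)
  } else {
    names_ <- gsub("'", "", toks[seq(1L, length(toks), by = 2L)])
    offsets <- as.integer(toks[seq(2L, length(toks), by = 2L)])
  }
  if (length(offsets) > 1L && any(diff(offsets) <= 0L))
    stop("header bundle offsets must be strictly increasing")
  cm <- regmatches(header,
                   regexpr("'curves_count'\\s*:\\s*[0-9]+", header))
  if (length(cm) == 0L) stop("header has no 'curves_count' attribute")
  curves_count <- as.integer(sub(".*:\\s*", "", cm))
  if (length(offsets) > 0L && any(offsets >= curves_count) &&
      curves_count > 0L)
    stop("header bundle offsets exceed curves_count")

  size <- file.size(p$data)
  con <- file(p$data, "rb")
  on.exit(close(con))
  fibers <- vector("list", curves_count)
  pos <- 0
  for (i in seq_len(curves_count)) {
    if (pos + 4 > size)
      stop("truncated payload: expected point count at byte ", pos)
    np <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(np) == 0L || np < 1L)
      stop("invalid point count at byte ", pos)
    pos <- pos + 4
    need <- 3 * np * 4
    if (pos + need > size)
      stop("truncated payload: fiber ", i, " needs ", need,
           " bytes at byte ", pos, ", file has ", size - pos)
    xyz <- readBin(con, "numeric", 3L * np, size = 4L, endian = "little")
    pos <- pos + need
    fibers[[i]] <- matrix(xyz, ncol = 3L, byrow = TRUE)
  }
  if (pos != size)
    warning("trailing bytes in payload after byte ", pos)
  if (curves_count == 0L)
    return(list(bundles = list(), labels = character(0L)))
  ends <- c(offsets[-1L], curves_count)
  bundles <- vector("list", length(names_))
  labels <- character(curves_count)
  for (k in seq_along(names_)) {
    idx <- (offsets[k] + 1L):ends[k]
    bundles[[k]] <- bundle(fibers[idx], label = names_[k])
    labels[idx] <- names_[k]
  }
  list(bundles = bundles, labels = labels)
}

#' Write the ground-truth manifest of a dataset
#'
#' JSON companion to the bundles file pair: the dataset seed and
#' specification, per-bundle parameters (label, fiber count, radii, noise
#' sigma), the per-fiber label vector and the crossing-pair registry.
#'
#' @param dataset A `fibersim_dataset`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(dataset, path) {
  stopifnot(inherits(dataset, "fibersim_dataset"))
  spec <- dataset$spec
  man <- list(
    format = "fibersim_manifest_1",
    seed = spec$seed,
    spec = spec[c("n_bundles", "r_end", "r_mid", "r_central", "fiber_range",
                  "sigma_range", "noise_mean", "min_length", "min_distance",
                  "crossing_threshold", "distribution")],
    bundles = lapply(seq_along(dataset$bundles), function(i) {
      list(label = dataset$bundles[[i]]$label,
           n_fibers = n_fibers(dataset$bundles[[i]]),
           radii = dataset$params[[i]]$radii,
           noise_sigma = dataset$params[[i]]$noise_sigma)
    }),
    fiber_labels = dataset$labels,
    crossing_pairs = unname(apply(dataset$crossing_pairs, 1L, identity,
                                  simplify = FALSE))
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a ground-truth manifest
#'
#' @param path Manifest JSON path.
#' @return The manifest as a named list with `crossing_pairs` restored to a
#'   2-column matrix and `fiber_labels` to an integer vector. Errors name
#'   the missing field on schema violations.
#' @export
read_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  required <- c("format", "spec", "bundles", "fiber_labels",
                "crossing_pairs")
  for (f in required)
    if (is.null(man[[f]]))
      stop("invalid manifest: missing field $.", f)
  for (f in c("n_bundles", "r_end", "sigma_range"))
    if (is.null(man$spec[[f]]))
      stop("invalid manifest: missing field $.spec.", f)
  man$fiber_labels <- as.integer(man$fiber_labels)
  cp <- man$crossing_pairs
  man$crossing_pairs <- if (length(cp) == 0L) {
    matrix(integer(0L), ncol = 2L, dimnames = list(NULL, c("a", "b")))
  } else {
    m <- do.call(rbind, lapply(cp, as.integer))
    dimnames(m) <- list(NULL, c("a", "b"))
    m
  }
  man
}
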
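#' Read a multi-model PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records is read as a single frame.  The roster (names, elements, residues)
#' is taken from the first model; later models contribute coordinates only.
#' Both `ATOM` and `HETATM` records are ingested.  Alternate locations other
#' than blank or `A` are dropped.  A blank element field is inferred from the
#' atom-name column (digits stripped, first letter kept), tolerating
#' minimised-structure exports.
#'
#' @param path Path to a PDB file.
#' @return A [trajectory()].
#' @seealso [read_frame_table()] for the plain-table dialect.
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"

  # keep only blank/'A' altlocs, mirroring the downstream mapping rules
  alt <- substr(lines, 17, 17)
  is_atom <- is_atom & (alt == " " | alt == "A")

  # validate coordinate fields up-front so parse errors carry line numbers
  for (i in which(is_atom)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (any(is.na(xyz))) {
      stop("unparsable coordinate field at line ", i, " of ", path,
           call. = FALSE)
    }
  }

  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) == 0) {
    counts <- sum(is_atom)
    if (counts == 0) stop("no ATOM/HETATM records in ", path, call. = FALSE)
    blocks <- list(which(is_atom))
    model_ids <- 1L
  } else {
    ends <- which(rec == "ENDMDL")
    if (length(ends) < length(model_starts)) {
      ends <- c(ends, length(lines) + 1L)
    }
    blocks <- vector("list", length(model_starts))
    model_ids <- integer(length(model_starts))
    for (k in seq_along(model_starts)) {
      rng <- seq(model_starts[k] + 1L, ends[k] - 1L)
      blocks[[k]] <- rng[is_atom[rng]]
      id <- suppressWarnings(as.integer(substr(lines[model_starts[k]], 7, 14)))
      model_ids[k] <- if (is.na(id)) k else id
    }
    n0 <- length(blocks[[1]])
    for (k in seq_along(blocks)) {
      if (length(blocks[[k]]) != n0) {
        stop(sprintf(
          "structural mismatch: model %d has %d atoms but model %d has %d",
          model_ids[k], length(blocks[[k]]), model_ids[1], n0), call. = FALSE)
      }
    }
  }

  # heavy lifting by the field's parser; bio3d keeps blank/'A' altlocs
  # (rm.alt) which matches the pre-scan above
  out <- utils::capture.output(
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                            verbose = FALSE)))
  at <- pdb$atom
  element <- trimws(as.character(at$elesy))
  blank <- is.na(element) | !nzchar(element)
  if (any(blank)) element[blank] <- infer_element(at$elety[blank])
  chain <- as.character(at$chain)
  chain[is.na(chain)] <- ""
  roster <- tibble::tibble(
    serial  = as.integer(at$eleno),
    name    = trimws(as.character(at$elety)),
    element = element,
    resname = trimws(as.character(at$resid)),
    resnum  = as.integer(at$resno),
    chain   = chain
  )
  xyz <- rbind(pdb$xyz)                    # n_models x 3N
  na_ <- nrow(roster)
  coords <- array(NA_real_, c(na_, 3, nrow(xyz)))
  for (k in seq_len(nrow(xyz))) {
    coords[, , k] <- matrix(xyz[k, ], na_, 3, byrow = TRUE)
  }
  trajectory(roster, coords)
}

# element symbol from a PDB atom name: strip digits/primes, first letter;
# two-letter symbols are only trusted from the element column, so "CA" -> C
infer_element <- function(name) {
  sym <- sub("^[^A-Za-z]*", "", name)
  toupper(substr(sym, 1, 1))
}

#' Read / write the frame-table trajectory dialect
#'
#' A lossless delimited-text dialect used for synthetic fixtures: one row per
#' atom per frame with header
#' `frame,serial,name,element,resname,resnum,chain,x,y,z` and an optional
#' `time_ps` column.  Frames are grouped by the `frame` index (ascending) and
#' the roster must be identical in every frame.
#'
#' @param path File path (CSV).
#' @return [read_frame_table()] returns a [trajectory()];
#'   [write_frame_table()] returns `path` invisibly.
#' @export
read_frame_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("frame", "serial", "name", "element", "resname", "resnum",
            "chain", "x", "y", "z")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0) {
    stop("frame table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tb) == 0) stop("no frames in ", path, call. = FALSE)
  tb <- dplyr::arrange(tb, .data$frame, .data$serial)
  frames <- unique(tb$frame)
  na_ <- sum(tb$frame == frames[1])
  if (nrow(tb) != na_ * length(frames)) {
    stop("structural mismatch: roster size differs between frames",
         call. = FALSE)
  }
  key <- function(d) paste(d$serial, d$name, d$resnum, d$chain, sep = "\r")
  k0 <- key(tb[tb$frame == frames[1], ])
  for (f in frames[-1]) {
    if (!identical(key(tb[tb$frame == f, ]), k0)) {
      stop("structural mismatch: roster differs in frame ", f, call. = FALSE)
    }
  }
  ros <- tb[tb$frame == frames[1],
            c("serial", "name", "element", "resname", "resnum", "chain")]
  coords <- array(NA_real_, c(na_, 3, length(frames)))
  coords[, 1, ] <- tb$x
  coords[, 2, ] <- tb$y
  coords[, 3, ] <- tb$z
  times <- NULL
  if ("time_ps" %in% names(tb)) {
    times <- tb$time_ps[match(frames, tb$frame)]
    if (any(is.na(times))) times <- NULL
  }
  trajectory(ros, coords, times)
}

#' @rdname read_frame_table
#' @param x A [trajectory()] to write.
#' @param digits Decimal places kept for coordinates (default 3, the PDB
#'   convention).
#' @export
write_frame_table <- function(x, path, digits = 3) {
  stopifnot(inherits(x, "trajectory"))
  tb <- as_tibble.trajectory(x)
  tb$x <- round(tb$x, digits)
  tb$y <- round(tb$y, digits)
  tb$z <- round(tb$z, digits)
  readr::write_csv(tb, path, progress = FALSE)
  invisible(path)
}
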
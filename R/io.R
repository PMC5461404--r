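#' Read and write trajectory tables
#'
#' CSV schema: cell_id, traj_id, frame, x_um, y_um and optionally state
#' (simulated data only).
#'
#' @param ts a [TrajectorySet-class].
#' @param path file path.
#' @param frameInterval ms, used when reading.
#' @return `readTrajectories` returns a [TrajectorySet-class].
#' @export
writeTrajectories <- function(ts, path) {
  r <- ts@records
  out <- data.frame(cell_id = r$cell_id, traj_id = r$traj_id,
                    frame = r$frame, x_um = r$x, y_um = r$y)
  if (!is.null(r$state)) out$state <- r$state
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTrajectories
#' @export
readTrajectories <- function(path, frameInterval = 2) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  rec <- data.frame(cell_id = d$cell_id, traj_id = d$traj_id,
                    frame = d$frame, x = d$x_um, y = d$y_um)
  if (!is.null(d$state)) rec$state <- d$state
  new("TrajectorySet", records = rec, frameInterval = frameInterval)
}

#' Read and write cell geometry tables
#'
#' CSV schema: cell_id, length_um, diameter_um.
#' @param cells data.frame in the schema above.
#' @param path file path.
#' @return `readCellGeometry` returns the data.frame.
#' @export
writeCellGeometry <- function(cells, path) {
  utils::write.csv(cells[, c("cell_id", "length_um", "diameter_um")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCellGeometry
#' @export
readCellGeometry <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an axial profile as TSV
#'
#' Columns: scaled_x_bin_center, probability.
#' @param profile an [AxialProfile-class].
#' @param path file path.
#' @export
writeAxialProfile <- function(profile, path) {
  e <- profile@binEdges
  ctr <- (e[-1] + e[-length(e)]) / 2
  utils::write.table(
    data.frame(scaled_x_bin_center = ctr,
               probability = profile@probability),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read displacement distributions as TSV
#'
#' Columns: bin_lo, bin_hi, count; header comment lines carry n_total
#' and kind.
#' @param dist a [DisplacementDistribution-class].
#' @param path file path.
#' @return `readDistribution` returns a
#'   [DisplacementDistribution-class].
#' @export
writeDistribution <- function(dist, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_total=%.10g kind=%s", dist@nTotal, dist@kind),
             con)
  e <- dist@binEdges
  utils::write.table(
    data.frame(bin_lo = e[-length(e)], bin_hi = e[-1],
               count = dist@counts),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDistribution
#' @export
readDistribution <- function(path) {
  hdr <- readLines(path, n = 1L)
  nTotal <- as.numeric(sub(".*n_total=([0-9.eE+-]+).*", "\\1", hdr))
  kind <- sub(".*kind=(\\S+).*", "\\1", hdr)
  d <- utils::read.delim(path, comment.char = "#")
  new("DisplacementDistribution",
      binEdges = c(d$bin_lo, d$bin_hi[nrow(d)]),
      counts = d$count, nTotal = nTotal, kind = kind)
}

#' Read a proteome table
#'
#' CSV schema: gene_id, copies_per_cell, plus either pro_pro_count and
#' length, or sequence (motifs counted on read). A FASTA file of protein
#' sequences plus a sidecar CSV (gene_id, copies_per_cell) is also
#' accepted.
#'
#' @param path CSV or FASTA path.
#' @param copiesPath sidecar CSV for FASTA input.
#' @return data.frame: gene_id, length, pro_pro_count, copies_per_cell.
#' @export
readProteome <- function(path, copiesPath = NULL) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    ids <- sub("^>\\s*(\\S+).*", "\\1", lines[hdr])
    starts <- hdr + 1L
    ends <- c(hdr[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(i)
      paste(lines[starts[i]:ends[i]], collapse = ""), character(1))
    if (is.null(copiesPath))
      stop("readProteome: FASTA input needs a copies sidecar CSV")
    cp <- utils::read.csv(copiesPath, stringsAsFactors = FALSE)
    copies <- cp$copies_per_cell[match(ids, cp$gene_id)]
    if (anyNA(copies)) stop("readProteome: missing copy numbers")
    pp <- vapply(seqs, function(s) countProPro(s)[["duets"]], integer(1))
    data.frame(gene_id = ids, length = nchar(seqs), pro_pro_count = pp,
               copies_per_cell = copies)
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (is.null(d$pro_pro_count) && !is.null(d$sequence)) {
      d$pro_pro_count <- vapply(d$sequence,
                                function(s) countProPro(s)[["duets"]],
                                integer(1))
      if (is.null(d$length)) d$length <- nchar(d$sequence)
    }
    d[, c("gene_id", "length", "pro_pro_count", "copies_per_cell")]
  }
}

#' Write a study bundle to a directory
#'
#' Writes cells.csv and trajectories.csv in the package schemas.
#' @param bundle a [generateStudy()] result.
#' @param dir output directory (created if needed).
#' @export
writeStudy <- function(bundle, dir) {
  stopifnot(inherits(bundle, "StudyBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCellGeometry(bundle$cells, file.path(dir, "cells.csv"))
  writeTrajectories(bundle$trajectories, file.path(dir, "trajectories.csv"))
  invisible(dir)
}
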
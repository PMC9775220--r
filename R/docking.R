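# Docking-pose distance and score statistics.

new_pose_set <- function(poses, scores) {
  ids <- vapply(poses, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("pose ids must be unique", call. = FALSE)
  stopifnot(all(c("pose_id", "score_kcal_mol") %in% names(scores)))
  structure(list(poses = poses, scores = scores), class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("<pose_set> %d poses\n", length(x$poses)))
  invisible(x)
}

#' Read a docking pose set (per-pose ligand PDBs plus a score table)
#'
#' Docking engines emit many dialects; this consumes the engine-neutral
#' layout of one ligand-only PDB file per pose (named `<pose_id>.pdb`)
#' under `pose_dir`, and a CSV score table with columns `pose_id`,
#' `score_kcal_mol`.
#'
#' @param pose_dir directory of per-pose PDB files
#' @param score_file CSV score table
#' @return a `"pose_set"`
#' @export
read_pose_set <- function(pose_dir, score_file) {
  if (!dir.exists(pose_dir)) stop("pose directory not found: ", pose_dir,
                                  call. = FALSE)
  scores <- utils::read.csv(score_file, stringsAsFactors = FALSE)
  if (!all(c("pose_id", "score_kcal_mol") %in% names(scores))) {
    stop("score table needs columns pose_id, score_kcal_mol", call. = FALSE)
  }
  poses <- lapply(scores$pose_id, function(id) {
    f <- file.path(pose_dir, paste0(id, ".pdb"))
    if (!file.exists(f)) stop("missing pose file: ", f, call. = FALSE)
    ens <- read_pdb_models(f)
    list(id = as.character(id), coords = conf_coords(ens, 1L),
         elements = ens$atoms$element)
  })
  new_pose_set(poses, scores)
}

#' Per-pose distance to a reference site
#'
#' Either the minimum ligand-heavy-atom distance to the site atom or the
#' distance of the ligand heavy-atom centroid.
#'
#' @param pose_set a `"pose_set"`
#' @param site length-3 site coordinates (Angstrom), e.g. from
#'   [atom_coords()] on the receptor
#' @param metric `"min-atom"` (default) or `"ligand-centroid"`
#' @return named numeric vector, one distance per pose
#' @export
pose_site_distances <- function(pose_set, site,
                                metric = c("min-atom", "ligand-centroid")) {
  metric <- match.arg(metric)
  site <- as.numeric(site)
  if (length(site) != 3L || any(!is.finite(site))) {
    stop("site must resolve to finite x, y, z coordinates", call. = FALSE)
  }
  out <- vapply(pose_set$poses, function(p) {
    heavy <- p$elements != "H"
    if (!any(heavy)) stop("pose ", p$id, " has no heavy atoms",
                          call. = FALSE)
    xyz <- p$coords[heavy, , drop = FALSE]
    if (metric == "min-atom") {
      sqrt(min(colSums((t(xyz) - site)^2)))
    } else {
      sqrt(sum((colMeans(xyz) - site)^2))
    }
  }, numeric(1))
  names(out) <- vapply(pose_set$poses, `[[`, character(1), "id")
  out
}

#' Histogram of pose-to-site distances with per-bin score summary
#'
#' Half-open bins `[lo + k w, lo + (k+1) w)`; a value exactly on an edge
#' goes to the right bin.  Out-of-range poses are counted in `overflow`,
#' never silently dropped.
#'
#' @param distances numeric distances (Angstrom)
#' @param bin_width bin width (Angstrom), default 0.5
#' @param range histogram range `c(lo, hi)`, default `c(2, 20)`
#' @param scores optional per-pose scores (kcal/mol) for the bin summary
#' @return list of class `"distance_histogram"`: `bin_edges`, `counts`,
#'   `overflow`, `score_summary` (data frame bin_lo, bin_hi, count,
#'   mean_score, min_score)
#' @export
distance_histogram <- function(distances, bin_width = 0.5,
                               range = c(2, 20), scores = NULL) {
  stopifnot(bin_width > 0, length(range) == 2L, range[2] > range[1])
  edges <- seq(range[1], range[2], by = bin_width)
  if (max(edges) < range[2]) edges <- c(edges, max(edges) + bin_width)
  nb <- length(edges) - 1L
  d <- as.numeric(distances)
  inside <- d >= edges[1] & d < edges[nb + 1L]
  idx <- floor((d[inside] - edges[1]) / bin_width) + 1L
  counts <- tabulate(idx, nbins = nb)
  summ <- data.frame(bin_lo = edges[-(nb + 1L)], bin_hi = edges[-1],
                     count = counts,
                     mean_score = NA_real_, min_score = NA_real_)
  if (!is.null(scores)) {
    stopifnot(length(scores) == length(d))
    sc <- split(scores[inside], factor(idx, levels = seq_len(nb)))
    summ$mean_score <- vapply(sc, function(v) {
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    summ$min_score <- vapply(sc, function(v) {
      if (length(v)) min(v) else NA_real_
    }, numeric(1))
  }
  structure(list(bin_edges = edges, counts = counts,
                 overflow = sum(!inside), score_summary = summ),
            class = "distance_histogram")
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf("<distance_histogram> %d bins, %d counted, %d overflow\n",
              length(x$counts), sum(x$counts), x$overflow))
  invisible(x)
}
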
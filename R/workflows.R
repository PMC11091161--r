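# Application workflows: ensemble distance matrices, Kabsch RMSD,
# complete-linkage clustering, reference-vs-model per-residue scoring,
# trajectory time series and Sarle's bimodality screening.

new_score_matrix <- function(values, labels, metric) {
  dimnames(values) <- list(labels, labels)
  structure(values, metric = metric, class = c("locohd_score_matrix", "matrix"))
}

check_score_matrix <- function(m) {
  stopifnot(isSymmetric(unclass(m)), all(diag(m) == 0))
  invisible(m)
}

#' All-vs-all LoCoHD matrices for a conformational ensemble
#'
#' Every structure is compared to every other at every primitive-atom
#' anchor (M anchors, N structures, M*N*(N-1)/2 scores). Environments are
#' built once per structure and reused across pairs.
#'
#' @param structures list of standardized `locohd_structure`s with
#'   identical atom inventories (same protein).
#' @param settings a [comparison_settings()]; the scheme is taken from it
#'   (the ensemble protocol uses the centroid-less FA or CG schemes).
#' @return list with `per_anchor` (list of M symmetric N x N matrices),
#'   `mean_matrix` (N x N mean over anchors), `anchor_means` (per-anchor
#'   mean over all pairs, named by anchor), `anchors` (data frame of anchor
#'   descriptors).
#' @export
ensemble_matrices <- function(structures, settings = comparison_settings("FA")) {
  N <- length(structures)
  if (N < 2L) stop_domain("an ensemble needs at least 2 structures")
  clouds <- lapply(structures, apply_scheme, scheme_name = settings$scheme_name)
  M <- nrow(clouds[[1L]])
  for (k in seq_along(clouds)) {
    if (nrow(clouds[[k]]) != M ||
        !identical(clouds[[k]]$ptype, clouds[[1L]]$ptype)) {
      stop_domain(paste("structure %d has a different primitive inventory;",
                        "standardize/prune the ensemble to a common set"), k)
    }
  }
  envs <- lapply(clouds, function(cl) {
    lapply(seq_len(M), function(i) build_environment(cl, i, settings))
  })
  per_anchor <- lapply(seq_len(M), function(i) matrix(0, N, N))
  labels <- sprintf("structure_%d", seq_len(N))
  for (a in seq_len(N - 1L)) {
    for (b in (a + 1L):N) {
      for (i in seq_len(M)) {
        s <- locohd_pair(envs[[a]][[i]], envs[[b]][[i]], settings$weight)
        per_anchor[[i]][a, b] <- s
        per_anchor[[i]][b, a] <- s
      }
    }
  }
  anchor_ids <- paste(clouds[[1L]]$res_key, clouds[[1L]]$ptype,
                      stats::ave(seq_len(M), clouds[[1L]]$res_key, FUN = seq_along),
                      sep = "#")
  per_anchor <- lapply(seq_len(M), function(i) {
    check_score_matrix(new_score_matrix(per_anchor[[i]], labels, "locohd"))
  })
  names(per_anchor) <- anchor_ids
  mean_mat <- Reduce(`+`, per_anchor) / M
  ut <- upper.tri(mean_mat)
  anchor_means <- vapply(per_anchor, function(m) mean(m[ut]), 0)
  list(per_anchor = per_anchor,
       mean_matrix = check_score_matrix(new_score_matrix(mean_mat, labels, "locohd")),
       anchor_means = anchor_means,
       anchors = clouds[[1L]][, c("ptype", "res_key")])
}

#' Kabsch superposition RMSD
#'
#' Optimal rigid-body superposition: both point sets are centered, the
#' optimal proper rotation is obtained from the SVD of the covariance
#' matrix with the usual determinant sign correction (reflections
#' disallowed), and the RMSD after superposition is returned.
#'
#' @param X,Y n x 3 coordinate matrices, n >= 3, matched row order.
#' @return RMSD in angstroms.
#' @export
kabsch_rmsd <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) stop_domain("coordinate sets differ in size")
  if (nrow(X) < 3L) stop_domain("need at least 3 points")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  s <- svd(crossprod(Yc, Xc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((Yc %*% R - Xc)^2)))
}

#' Pairwise RMSD matrix over primitive-atom coordinates
#'
#' Uses the same primitive atoms as the LoCoHD run (the published ensemble
#' protocol) unless `ca_only = TRUE`, which superposes the structures'
#' C-alpha atoms instead.
#'
#' @param structures list of standardized structures, identical inventories.
#' @param scheme_name typing scheme providing the coordinates.
#' @param ca_only superpose C-alpha atoms of the raw structures instead.
#' @return symmetric zero-diagonal `locohd_score_matrix` (metric `"rmsd"`).
#' @export
rmsd_matrix <- function(structures, scheme_name = "FA", ca_only = FALSE) {
  N <- length(structures)
  if (N < 2L) stop_domain("need at least 2 structures")
  coords <- if (ca_only) {
    lapply(structures, function(s) {
      as.matrix(s[s$atom_name == "CA", c("x", "y", "z")])
    })
  } else {
    lapply(structures, function(s) {
      cl <- apply_scheme(s, scheme_name)
      as.matrix(cl[, c("x", "y", "z")])
    })
  }
  n0 <- nrow(coords[[1L]])
  if (any(vapply(coords, nrow, 1L) != n0)) {
    stop_domain("structures yield different primitive atom counts")
  }
  m <- matrix(0, N, N)
  for (a in seq_len(N - 1L)) for (b in (a + 1L):N) {
    m[a, b] <- m[b, a] <- kabsch_rmsd(coords[[a]], coords[[b]])
  }
  check_score_matrix(new_score_matrix(m, sprintf("structure_%d", seq_len(N)),
                                      "rmsd"))
}

#' Complete-linkage agglomerative clustering of a distance matrix
#'
#' Thin wrapper over [stats::hclust()] with `method = "complete"`; the cut
#' is either at a distance threshold (clusters are groups whose merge
#' height does not exceed it) or at a fixed cluster count.
#'
#' @param m symmetric distance matrix (e.g. a `locohd_score_matrix`).
#' @param threshold distance threshold for the cut (used if `k` missing).
#' @param k number of clusters.
#' @return integer cluster labels, one per structure.
#' @export
complete_linkage <- function(m, threshold = NULL, k = NULL) {
  n <- nrow(m)
  if (!is.null(k) && k > n) stop_domain("k = %d exceeds N = %d", k, n)
  hc <- stats::hclust(stats::as.dist(m), method = "complete")
  if (!is.null(k)) {
    stats::cutree(hc, k = k)
  } else if (!is.null(threshold)) {
    stats::cutree(hc, h = threshold)
  } else {
    stop_config("supply either threshold or k")
  }
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks. Constant input has no defined rank
#' correlation; `NA` is returned (never a silent 0).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho, or `NA_real_` when undefined.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop_domain("x and y differ in length")
  if (length(x) < 3L) stop_domain("need at least 3 observations")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(rank(x), rank(y))
}

#' Per-residue LoCoHD between a reference and a model
#'
#' Scores corresponding residues through their centroid (Cent) anchors —
#' the model-quality protocol — and joins an optional externally computed
#' per-residue score table (e.g. lDDT) by residue identity. Inputs must
#' already be chain-paired and pruned to a common inventory
#' ([pair_chains()] + [prune_to_common()]); residues are then corresponding
#' by position.
#'
#' @param reference,model pruned `locohd_structure`s.
#' @param settings a [comparison_settings()] with a `+Cent` scheme.
#' @param external_scores optional data frame with columns `chain`,
#'   `resnum`, `icode`, `score` (extra columns ignored), keyed on the
#'   reference numbering.
#' @return list with `table` (per-residue data frame: chain, resnum, icode,
#'   resname, locohd, and `external` when supplied) and `summary`
#'   (`prm_locohd` = per-structure median LoCoHD, `prm_external`,
#'   `spearman`, `n_unjoined`).
#' @export
score_model_pair <- function(reference, model,
                             settings = comparison_settings("FA+Cent"),
                             external_scores = NULL) {
  if (!grepl("\\+Cent$", settings$scheme_name)) {
    stop_domain("score_model_pair requires a +Cent scheme for centroid anchors")
  }
  ra <- apply_scheme(reference, settings$scheme_name)
  ma <- apply_scheme(model, settings$scheme_name)
  pairs <- default_anchor_pairs(ra, ma, "centroid")
  scores <- compare_clouds(ra, ma, pairs, settings)

  keys <- residue_keys(reference)
  parts <- strsplit(keys, "|", fixed = TRUE)
  tab <- data.frame(
    chain = vapply(parts, `[[`, "", 1L),
    resnum = as.integer(vapply(parts, `[[`, "", 2L)),
    icode = vapply(parts, `[[`, "", 3L),
    resname = vapply(parts, `[[`, "", 4L),
    locohd = scores,
    stringsAsFactors = FALSE
  )
  summary <- list(prm_locohd = stats::median(tab$locohd),
                  prm_external = NA_real_, spearman = NA_real_,
                  n_unjoined = 0L)
  if (!is.null(external_scores)) {
    key_tab <- paste(tab$chain, tab$resnum, trimws(tab$icode))
    key_ext <- paste(external_scores$chain, external_scores$resnum,
                     trimws(as.character(external_scores$icode)))
    tab$external <- external_scores$score[match(key_tab, key_ext)]
    summary$n_unjoined <- sum(is.na(tab$external))
    if (summary$n_unjoined) {
      message(sprintf("score_model_pair: %d residue(s) without external score dropped from summary",
                      summary$n_unjoined))
    }
    ok <- !is.na(tab$external)
    summary$prm_external <- stats::median(tab$external[ok])
    summary$spearman <- if (sum(ok) >= 3L) spearman(tab$locohd[ok], tab$external[ok]) else NA_real_
  }
  list(table = tab, summary = summary)
}

#' Per-anchor LoCoHD time series along a trajectory
#'
#' Each (strided) frame is compared to a fixed reference frame, anchor by
#' anchor, through residue-centroid anchors — the trajectory protocol.
#'
#' @param frames list of standardized structures (trajectory frames),
#'   identical inventories.
#' @param reference_index index of the reference frame (default first).
#' @param settings a [comparison_settings()] with a `+Cent` scheme
#'   (protocol default CG+Cent).
#' @param stride keep every `stride`-th frame (starting at the first).
#' @return matrix of scores, rows = anchors (named by residue key), columns
#'   = analyzed frame indices; class `locohd_series`.
#' @export
trajectory_series <- function(frames, reference_index = 1L,
                              settings = comparison_settings("CG+Cent"),
                              stride = 1L) {
  if (reference_index < 1L || reference_index > length(frames)) {
    stop_domain("reference_index %d out of range", reference_index)
  }
  if (stride < 1L || stride > length(frames)) {
    stop_domain("stride %d invalid for %d frames", stride, length(frames))
  }
  sel <- seq(1L, length(frames), by = stride)
  clouds <- lapply(frames, apply_scheme, scheme_name = settings$scheme_name)
  ref_cloud <- clouds[[reference_index]]
  ref_envs <- NULL
  anchor_keys <- ref_cloud$res_key[ref_cloud$ptype == "Cent"]
  out <- matrix(NA_real_, nrow = length(anchor_keys), ncol = length(sel),
                dimnames = list(anchor_keys, sprintf("frame_%d", sel)))
  for (j in seq_along(sel)) {
    cl <- clouds[[sel[j]]]
    pairs <- default_anchor_pairs(ref_cloud, cl, "centroid")
    if (is.null(ref_envs)) {
      ref_envs <- lapply(pairs[, 1L], function(i) build_environment(ref_cloud, i, settings))
    }
    out[, j] <- vapply(seq_len(nrow(pairs)), function(i) {
      locohd_pair(ref_envs[[i]],
                  build_environment(cl, pairs[i, 2L], settings),
                  settings$weight)
    }, 0)
  }
  structure(out, reference_index = reference_index, stride = stride,
            class = c("locohd_series", "matrix"))
}

#' Sarle's bimodality coefficient
#'
#' `beta = (gamma^2 + 1) / kappa` with moment-based sample skewness
#' `gamma = m3 / m2^(3/2)` and non-excess kurtosis `kappa = m4 / m2^2`
#' (central moments with divisor n). The uniform distribution gives the
#' reference value 5/9 ~= 0.555; values above it suggest bimodality
#' (a symmetric two-point distribution attains the maximum 1, a Gaussian
#' gives 1/3). The non-excess convention is forced by that uniform
#' reference.
#'
#' @param samples numeric vector, length >= 4, non-constant.
#' @return list with `beta`, `skewness`, `kurtosis`.
#' @export
bimodality <- function(samples) {
  n <- length(samples)
  if (n < 4L) stop_domain("bimodality needs at least 4 samples")
  m <- mean(samples)
  m2 <- mean((samples - m)^2)
  if (m2 == 0) stop_domain("bimodality undefined for a constant sample")
  g <- mean((samples - m)^3) / m2^1.5
  k <- mean((samples - m)^4) / m2^2
  list(beta = (g^2 + 1) / k, skewness = g, kurtosis = k)
}

#' Rank trajectory anchors by bimodality
#'
#' @param series a `locohd_series` matrix (rows = anchors) or a named list
#'   of numeric score vectors.
#' @param reference flag level; anchors with `beta` above it are marked
#'   `flagged` (uniform-distribution reference 5/9).
#' @return data frame (anchor, beta, skewness, kurtosis, flagged) sorted by
#'   descending beta, ties broken by anchor id.
#' @export
rank_bimodal <- function(series, reference = 5 / 9) {
  if (is.matrix(series)) {
    if (inherits(series, "locohd_series")) {
      # the reference frame's self-comparison is identically 0 by
      # construction, not a draw from the anchor's score distribution;
      # exclude it from the moment statistics
      ref_col <- sprintf("frame_%d", attr(series, "reference_index"))
      series <- series[, setdiff(colnames(series), ref_col), drop = FALSE]
    }
    series <- stats::setNames(lapply(seq_len(nrow(series)), function(i) series[i, ]),
                              rownames(series))
  }
  if (!length(series)) {
    return(data.frame(anchor = character(0), beta = numeric(0),
                      skewness = numeric(0), kurtosis = numeric(0),
                      flagged = logical(0)))
  }
  rows <- lapply(names(series), function(id) {
    b <- tryCatch(bimodality(series[[id]]),
                  locohd_domain_error = function(e) {
                    # constant series: no spread, no defined coefficient
                    list(beta = NA_real_, skewness = NA_real_, kurtosis = NA_real_)
                  })
    data.frame(anchor = id, beta = b$beta, skewness = b$skewness,
               kurtosis = b$kurtosis, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$beta, out$anchor), , drop = FALSE]
  out$flagged <- !is.na(out$beta) & out$beta > reference
  rownames(out) <- NULL
  out
}
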
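# Synthetic fixtures: toy primitive clouds, minimal PDB files with
# placeholder side chains, noise-perturbed ensembles with planted clusters,
# and two-state trajectories. Everything is a pure function of its
# arguments (seed included), so repeated generation is byte-identical.
# Side-chain geometry is deliberately crude: the metric consumes only typed
# points and distances, so correct atom names at approximate positions are
# enough; these are not physical models.

with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Toy primitive clouds
#'
#' `kind = "worked_example"` returns the canonical 4-atom example used
#' throughout the documentation and tests: types (A, A, B, B) at distances
#' (0, 1, 3, 5) angstroms from the first atom, with residue sources
#' (X, X, Y, Z), over the type set \{A, B, C\}. `kind = "random"` places `n`
#' atoms uniformly in a cube of edge `box`, with uniformly drawn types and
#' one single-atom residue source each.
#'
#' @param kind `"worked_example"` or `"random"`.
#' @param n atom count for random clouds (must be >= 1).
#' @param type_set type labels for random clouds.
#' @param n_residues number of distinct residue sources for random clouds.
#' @param box cube edge length, angstroms.
#' @param seed integer seed (random clouds).
#' @return a `locohd_cloud` (scheme `"toy"`).
#' @export
make_cloud <- function(kind = c("worked_example", "random"), n = 10L,
                       type_set = c("A", "B", "C"), n_residues = n,
                       box = 12, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "worked_example") {
    return(new_cloud(ptype = c("A", "A", "B", "B"),
                     x = c(0, 1, 3, 5), y = rep(0, 4), z = rep(0, 4),
                     res_key = c("X", "X", "Y", "Z"),
                     scheme = "toy", type_set = c("A", "B", "C"),
                     provenance = "worked_example"))
  }
  if (n < 1L) stop_empty("a cloud needs at least one atom")
  if (!length(type_set)) stop_config("empty type set")
  with_seed(seed, {
    new_cloud(ptype = sample(type_set, n, replace = TRUE),
              x = stats::runif(n, 0, box), y = stats::runif(n, 0, box),
              z = stats::runif(n, 0, box),
              res_key = paste0("R", sample(seq_len(n_residues), n, replace = TRUE)),
              scheme = "toy", type_set = type_set,
              provenance = sprintf("random(seed=%d)", seed))
  })
}

#' Write a minimal synthetic PDB file
#'
#' Builds an idealized backbone (extended strand or a helix-like spiral)
#' for a one-letter sequence and attaches placeholder side-chain atoms with
#' correct PDB names, then writes a standard fixed-width PDB. The file
#' round-trips through [read_structure()] and passes the typing coverage
#' audits; it is not a physically sensible conformation.
#'
#' @param sequence one-letter sequence over the 20 canonical letters.
#' @param geometry `"extended"` or `"helix"`.
#' @param seed seed for the side-chain jitter.
#' @param path output path (default: a tempfile).
#' @param chain chain identifier.
#' @return the path, invisibly; the structure object as attribute
#'   `"structure"`.
#' @export
make_pdb <- function(sequence, geometry = c("extended", "helix"), seed = 1L,
                     path = tempfile(fileext = ".pdb"), chain = "A") {
  geometry <- match.arg(geometry)
  letters1 <- strsplit(sequence, "")[[1L]]
  if (!length(letters1)) stop_domain("empty sequence")
  bad <- setdiff(letters1, names(AA3_FROM_1))
  if (length(bad)) stop_domain("invalid residue letter(s): %s", paste(bad, collapse = ""))
  res3 <- unname(AA3_FROM_1[letters1])
  s <- make_structure_from_sequence(res3, geometry, seed, chain)
  write_pdb(s, path)
  invisible(structure(path, structure = s))
}

make_structure_from_sequence <- function(res3, geometry, seed, chain = "A") {
  with_seed(seed, {
    rows <- list()
    for (i in seq_along(res3)) {
      ca <- if (geometry == "extended") {
        c(3.8 * (i - 1L), 0.6 * (i %% 2L), 0)
      } else {
        ang <- 100 * pi / 180 * (i - 1L)
        c(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * (i - 1L))
      }
      bb <- rbind(N = ca + c(-1.20, 0.75, 0.00),
                  CA = ca,
                  C = ca + c(1.25, 0.65, 0.00),
                  O = ca + c(1.45, 1.85, 0.15))
      sc_names <- SIDECHAIN_ATOMS[[res3[i]]]
      # placeholder side chain: march away from CA with mild seeded jitter
      dirv <- c(0.25, -0.85, 0.47) + stats::rnorm(3, 0, 0.05)
      dirv <- dirv / sqrt(sum(dirv^2))
      sc <- if (length(sc_names)) {
        t(vapply(seq_along(sc_names), function(k) {
          ca + dirv * (1.2 + 0.85 * (k - 1L)) + stats::rnorm(3, 0, 0.12)
        }, numeric(3)))
      } else {
        matrix(numeric(0), ncol = 3L)
      }
      names_all <- c(rownames(bb), sc_names)
      xyz <- rbind(bb, sc)
      rows[[i]] <- data.frame(
        chain = chain, resnum = i, icode = "", resname = res3[i],
        atom_name = names_all, element = element_from_name(names_all),
        altloc = "", occupancy = 1,
        x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
        stringsAsFactors = FALSE)
    }
    new_structure(do.call(rbind, rows), 1L)
  })
}

#' Noise-perturbed ensemble with optional planted clusters
#'
#' Members are the base structure plus iid isotropic Gaussian coordinate
#' noise. With `n_clusters > 1`, members are assigned to clusters
#' round-robin and each cluster (beyond the first) rigidly shifts the
#' second half of the residues by `cluster_shift` angstroms along a
#' cluster-specific axis before the noise is added — a planted block
#' structure recoverable by clustering.
#'
#' @param base a `locohd_structure`.
#' @param n_structures ensemble size (>= 2).
#' @param noise_sigma per-coordinate noise standard deviation, angstroms.
#' @param n_clusters planted cluster count.
#' @param cluster_shift sub-domain shift magnitude, angstroms.
#' @param seed integer seed.
#' @return list of structures; planted labels in attribute
#'   `"cluster_labels"`.
#' @export
make_ensemble <- function(base, n_structures, noise_sigma = 0.3,
                          n_clusters = 1L, cluster_shift = 0, seed = 1L) {
  if (n_structures < 2L) stop_domain("an ensemble needs >= 2 members")
  keys <- residue_keys(base)
  half_start <- ceiling(length(keys) / 2) + 1L
  movable <- if (half_start <= length(keys)) {
    base$res_key %in% keys[half_start:length(keys)]
  } else {
    rep(TRUE, nrow(base))
  }
  labels <- rep(seq_len(max(n_clusters, 1L)), length.out = n_structures)
  axes <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  with_seed(seed, {
    members <- lapply(seq_len(n_structures), function(k) {
      a <- as.data.frame(base)
      cl <- labels[k]
      if (cl > 1L && cluster_shift > 0) {
        ax <- axes[((cl - 2L) %% 3L) + 1L, ]
        a$x[movable] <- a$x[movable] + ax[1L] * cluster_shift
        a$y[movable] <- a$y[movable] + ax[2L] * cluster_shift
        a$z[movable] <- a$z[movable] + ax[3L] * cluster_shift
      }
      n <- nrow(a)
      a$x <- a$x + stats::rnorm(n, 0, noise_sigma)
      a$y <- a$y + stats::rnorm(n, 0, noise_sigma)
      a$z <- a$z + stats::rnorm(n, 0, noise_sigma)
      new_structure(a, k)
    })
    structure(members, cluster_labels = labels)
  })
}

#' Two-state synthetic trajectory
#'
#' Frames are the base structure plus Gaussian noise; from `switch_frame`
#' on, the side-chain (non-backbone) atoms of one residue are additionally
#' displaced by `displacement` angstroms, creating a two-level score series
#' for anchors near the switching group.
#'
#' @param base a `locohd_structure`.
#' @param n_frames number of frames.
#' @param switch_frame first frame of the displaced state.
#' @param switch_residue residue ordinal (1-based, file order) or residue
#'   key of the switching residue.
#' @param displacement displacement magnitude, angstroms (applied along x).
#' @param noise_sigma per-coordinate noise sd, angstroms.
#' @param seed integer seed.
#' @return list of structures; the switching residue key in attribute
#'   `"switch_res_key"`, the switch frame in `"switch_frame"`.
#' @export
make_trajectory <- function(base, n_frames, switch_frame,
                            switch_residue, displacement = 4,
                            noise_sigma = 0.15, seed = 1L) {
  if (switch_frame < 1L || switch_frame > n_frames) {
    stop_domain("switch_frame %d outside 1..%d", switch_frame, n_frames)
  }
  keys <- residue_keys(base)
  key <- if (is.numeric(switch_residue)) {
    if (switch_residue < 1L || switch_residue > length(keys)) {
      stop_domain("switch_residue ordinal %d out of range", switch_residue)
    }
    keys[switch_residue]
  } else {
    if (!switch_residue %in% keys) stop_domain("unknown residue '%s'", switch_residue)
    switch_residue
  }
  target <- base$res_key == key & !(base$atom_name %in% BACKBONE_ATOMS)
  if (!any(target)) target <- base$res_key == key  # Gly: move the whole residue
  with_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(f) {
      a <- as.data.frame(base)
      if (f >= switch_frame) a$x[target] <- a$x[target] + displacement
      n <- nrow(a)
      a$x <- a$x + stats::rnorm(n, 0, noise_sigma)
      a$y <- a$y + stats::rnorm(n, 0, noise_sigma)
      a$z <- a$z + stats::rnorm(n, 0, noise_sigma)
      new_structure(a, f)
    })
    structure(frames, switch_res_key = key, switch_frame = switch_frame)
  })
}
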
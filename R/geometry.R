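# Kabsch least-squares rigid-body fit of b onto a (both n x 3, paired rows).
# Returns rotation R and translation t such that b %*% R + t approximates a.
kabsch_fit <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  h <- crossprod(b0, a0)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = rot, translation = ca - cb %*% rot,
       singular_values = s$d)
}

apply_rigid <- function(x, fit) {
  sweep(x %*% fit$rotation, 2, as.vector(fit$translation), "+", check.margin = FALSE)
}

#' Superpose two structure models (Kabsch, with optional outlier pruning)
#'
#' Pairs atoms of the two models by (chain, residue number, atom name),
#' restricted to `atoms` (default the CA trace), and computes the
#' least-squares rigid-body fit. When `prune_cutoff` is set, the fit is
#' made robust by iteratively removing the single worst-fitting pair whose
#' residual exceeds the cutoff and refitting, until all remaining
#' residuals are within the cutoff (never below 3 pairs). This mirrors the
#' "pruned atoms" reporting convention of structural-alignment tools.
#'
#' @param model_a,model_b `structure_model`s (model 1 of each is used).
#' @param atoms Atom-name selection: a character vector of atom names
#'   (e.g. `"CA"`), or `"heavy"` for all heavy atoms.
#' @param prune_cutoff Optional residual cutoff in Angstroms (a common
#'   robust-fit choice is 2.0).
#' @return A `superposition` object: list with `rmsd` (Angstroms, over the
#'   retained pairs), `n_atoms_used`, `n_pruned`, `rotation`,
#'   `translation`, and `degenerate` flag (near-collinear atom sets are
#'   fitted but flagged).
#' @export
superpose_structures <- function(model_a, model_b, atoms = "CA",
                                 prune_cutoff = NULL) {
  pa <- select_named_atoms(model_a, atoms)
  pb <- select_named_atoms(model_b, atoms)
  key_a <- paste(pa$chain, pa$resno, pa$elety)
  key_b <- paste(pb$chain, pb$resno, pb$elety)
  common <- intersect(key_a, key_b)
  if (length(common) < 3L) {
    abort("Fewer than 3 paired atoms; cannot superpose.")
  }
  a <- coords_matrix(pa[match(common, key_a), ])
  b <- coords_matrix(pb[match(common, key_b), ])
  keep <- seq_along(common)
  repeat {
    fit <- kabsch_fit(a[keep, , drop = FALSE], b[keep, , drop = FALSE])
    resid <- sqrt(rowSums((apply_rigid(b[keep, , drop = FALSE], fit) -
                             a[keep, , drop = FALSE])^2))
    if (is.null(prune_cutoff) || max(resid) <= prune_cutoff ||
        length(keep) <= 3L) break
    keep <- keep[-which.max(resid)]
  }
  rmsd <- sqrt(mean(resid^2))
  sv <- fit$singular_values
  degenerate <- sv[2] < 1e-8 * max(sv[1], 1)
  if (degenerate) warn("Near-collinear atom set; superposition is ill-determined.")
  structure(
    list(rmsd = rmsd, n_atoms_used = length(keep),
         n_pruned = length(common) - length(keep),
         rotation = fit$rotation, translation = as.vector(fit$translation),
         degenerate = degenerate),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> RMSD = %.4f A over %d atoms (%d pruned)\n",
              x$rmsd, x$n_atoms_used, x$n_pruned))
  invisible(x)
}

select_named_atoms <- function(model, atoms) {
  h <- heavy_atoms(model)
  if (identical(atoms, "heavy")) h else filter(h, .data$elety %in% atoms)
}

#' Interface residues between two residue ranges
#'
#' All residue pairs, one from each (disjoint) range, with any heavy-atom
#' distance at or below `cutoff`. Used, e.g., to recover the
#' pseudokinase–kinase autoinhibition interface of a closed kinase model.
#' The pair set is symmetric in the two ranges.
#'
#' @param model A `structure_model`.
#' @param range_a,range_b Integer vectors of residue numbers (disjoint).
#' @param cutoff Heavy-atom distance cutoff in Angstroms (default 5.0).
#' @return Tibble `res_a`, `res_b`, `min_dist`, sorted by `min_dist`.
#' @export
interface_residues <- function(model, range_a, range_b, cutoff = 5.0) {
  if (length(intersect(range_a, range_b)) > 0L) {
    abort("Residue ranges overlap.")
  }
  h <- heavy_atoms(model)
  aa <- filter(h, .data$resno %in% range_a)
  bb <- filter(h, .data$resno %in% range_b)
  if (nrow(aa) == 0L || nrow(bb) == 0L) {
    return(tibble(res_a = integer(), res_b = integer(), min_dist = numeric()))
  }
  d <- sqrt(cross_dist2(coords_matrix(aa), coords_matrix(bb)))
  pairs <- expand.grid(i = seq_len(nrow(aa)), j = seq_len(nrow(bb)))
  tibble(
    res_a = aa$resno[pairs$i], res_b = bb$resno[pairs$j],
    dist = as.vector(d)
  ) |>
    group_by(.data$res_a, .data$res_b) |>
    summarise(min_dist = min(.data$dist), .groups = "drop") |>
    filter(.data$min_dist <= cutoff) |>
    arrange(.data$min_dist)
}

#' Contacts of a focal residue
#'
#' Lists every other residue with a heavy-atom distance at or below
#' `cutoff_contact` from the focal residue, sorted by distance, and flags
#' hydrogen-bond-capable partners: a donor/acceptor heavy-atom pair (N or
#' O on both sides) within `cutoff_hbond`. This is a distance-only proxy
#' (no angle term), appropriate for predicted models without hydrogens.
#'
#' @param model A `structure_model`.
#' @param position Residue number of the focal residue.
#' @param chain Optional chain of the focal residue.
#' @param cutoff_contact Contact cutoff in Angstroms (default 5.0).
#' @param cutoff_hbond Donor/acceptor cutoff in Angstroms (default 3.5).
#' @return A tibble (`contact_report`): `chain`, `resno`, `resid`,
#'   `min_dist`, `hbond_capable`, sorted by `min_dist`.
#' @export
residue_contacts <- function(model, position, chain = NULL,
                             cutoff_hbond = 3.5, cutoff_contact = 5.0) {
  h <- filter(heavy_atoms(model), !.data$het)
  focal <- filter(h, .data$resno == position)
  if (!is.null(chain)) focal <- filter(focal, .data$chain == !!chain)
  if (nrow(focal) == 0L) abort(sprintf("Residue %s not found.", position))
  fkeys <- unique(paste(focal$chain, focal$resno))
  others <- filter(h, !paste(.data$chain, .data$resno) %in% fkeys)
  if (nrow(others) == 0L) {
    return(structure(tibble(chain = character(), resno = integer(),
                            resid = character(), min_dist = numeric(),
                            hbond_capable = logical()),
                     class = c("contact_report", class(tibble()))))
  }
  d <- sqrt(cross_dist2(coords_matrix(focal), coords_matrix(others)))
  focal_no <- focal$element %in% c("N", "O")
  other_no <- others$element %in% c("N", "O")
  hb_mat <- d <= cutoff_hbond & outer(focal_no, other_no, "&")
  rep_tbl <- tibble(
    chain = rep(others$chain, each = nrow(focal)),
    resno = rep(others$resno, each = nrow(focal)),
    resid = rep(others$resid, each = nrow(focal)),
    dist = as.vector(d),
    hb = as.vector(hb_mat)
  ) |>
    group_by(.data$chain, .data$resno, .data$resid) |>
    summarise(min_dist = min(.data$dist), hbond_capable = any(.data$hb),
              .groups = "drop") |>
    filter(.data$min_dist <= cutoff_contact) |>
    arrange(.data$min_dist)
  structure(rep_tbl, focal = position,
            class = c("contact_report", class(rep_tbl)))
}

#' Binding-pocket center and residue-to-pocket distances
#'
#' `pocket_center()` defines a pocket as the centroid of the heavy atoms
#' of a bound ligand (HET residue name) or of a user-supplied residue set.
#' `distance_to_pocket()` measures from a residue's side-chain centroid
#' (heavy atoms from CB outward; CA fallback for glycine) to the pocket
#' center — e.g. the distance of each activation-loop tyrosine to the
#' center of the ADP pocket.
#'
#' @param model A `structure_model`.
#' @param ligand HET residue name defining the pocket (e.g. `"ADP"`).
#' @param residues Alternative: integer residue numbers defining the pocket.
#' @return `pocket_center()`: a `pocket_spec` list with `center` (length-3
#'   numeric) and `n_atoms`. `distance_to_pocket()`: distance in Angstroms.
#' @export
pocket_center <- function(model, ligand = NULL, residues = NULL) {
  h <- heavy_atoms(model)
  def <- if (!is.null(ligand)) {
    filter(h, .data$het, .data$resid == ligand)
  } else if (!is.null(residues)) {
    filter(h, .data$resno %in% residues)
  } else {
    abort("Supply `ligand` or `residues` to define the pocket.")
  }
  if (nrow(def) == 0L) abort("No defining atoms found for the pocket.")
  structure(list(center = colMeans(coords_matrix(def)), n_atoms = nrow(def)),
            class = "pocket_spec")
}

#' @rdname pocket_center
#' @param position Residue number whose distance to the pocket is wanted.
#' @param pocket A `pocket_spec` from `pocket_center()`.
#' @export
distance_to_pocket <- function(model, position, pocket) {
  stopifnot(inherits(pocket, "pocket_spec"))
  h <- heavy_atoms(model)
  res <- filter(h, .data$resno == position, !.data$het)
  if (nrow(res) == 0L) abort(sprintf("Residue %d not found.", position))
  backbone <- c("N", "CA", "C", "O", "OXT")
  side <- filter(res, !.data$elety %in% backbone)
  ref <- if (nrow(side) > 0L) colMeans(coords_matrix(side)) else {
    ca <- filter(res, .data$elety == "CA")
    if (nrow(ca) == 0L) colMeans(coords_matrix(res)) else
      as.vector(coords_matrix(ca)[1, ])
  }
  sqrt(sum((ref - pocket$center)^2))
}

#' Per-residue fluctuation over a coordinate ensemble
#'
#' Root-mean-square fluctuation of each residue's CA atom around its
#' ensemble-mean position, over the models of a multi-model structure:
#' \eqn{\mathrm{RMSF}_i = \sqrt{\langle |r_i(t) - \bar r_i|^2 \rangle_t}}.
#' With `fit = TRUE`, every frame is first superposed onto frame 1 on the
#' CA trace, removing rigid-body drift; the default `fit = FALSE` measures
#' raw deviation from the mean coordinates, matching the convention of
#' computing fluctuation for each structure independently.
#'
#' @param model A multi-model `structure_model` (at least 2 models).
#' @param fit Superpose each frame onto frame 1 first?
#' @param atom Atom name used per residue (default `"CA"`).
#' @return An `rmsf_profile` tibble: `chain`, `resno`, `rmsf` (Angstroms).
#' @export
ensemble_rmsf <- function(model, fit = FALSE, atom = "CA") {
  stopifnot(inherits(model, "structure_model"))
  if (model$n_models < 2L) abort("RMSF needs an ensemble of at least 2 models.")
  frames <- purrr::map(seq_len(model$n_models), function(m) {
    am <- filter(model$atoms, .data$model == m, .data$elety == atom, !.data$het)
    am <- arrange(am, .data$chain, .data$resno)
    am
  })
  ref_key <- paste(frames[[1]]$chain, frames[[1]]$resno)
  for (f in frames[-1]) {
    if (!identical(paste(f$chain, f$resno), ref_key)) {
      abort("Inconsistent residue sets across models.")
    }
  }
  mats <- purrr::map(frames, coords_matrix)
  if (fit) {
    mats <- c(mats[1], purrr::map(mats[-1], function(m) {
      apply_rigid(m, kabsch_fit(mats[[1]], m))
    }))
  }
  arr <- simplify2array(mats)           # n_res x 3 x n_frames
  mean_xyz <- apply(arr, c(1, 2), mean)
  dev2 <- apply(seq_len(dim(arr)[3]) |> vapply(function(t) {
    rowSums((arr[, , t] - mean_xyz)^2)
  }, numeric(nrow(mean_xyz))), 1, mean)
  out <- tibble(chain = frames[[1]]$chain, resno = frames[[1]]$resno,
                rmsf = sqrt(dev2))
  structure(out, class = c("rmsf_profile", class(out)))
}
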
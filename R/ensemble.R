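#' Coordinate ensemble container
#'
#' Holds M snapshots of Calpha positions for a (pseudo)tetrameric channel
#' plus optional water-oxygen coordinates per snapshot, the reference
#' model used for superposition, and the channel axis.
#'
#' @param coords Numeric array `M x N x 3` of Calpha positions
#'   (Angstrom), N atoms per snapshot.
#' @param residue Integer vector length N: residue index within a subunit.
#' @param subunit Integer vector length N: subunit index (1-based).
#' @param waters Optional list of length M; element m is a `k_m x 3`
#'   matrix of water oxygen positions in snapshot m (may be `NULL`).
#' @param reference `N x 3` reference model (default: first snapshot).
#' @param axis Channel axis unit vector (default z).
#' @return Object of class `"coord_ensemble"`.
#' @export
coord_ensemble <- function(coords, residue, subunit, waters = NULL,
                           reference = NULL, axis = c(0, 0, 1)) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  n <- dim(coords)[2]
  stopifnot(length(residue) == n, length(subunit) == n)
  if (!is.null(waters)) stopifnot(length(waters) == dim(coords)[1])
  if (is.null(reference)) reference <- coords[1, , , drop = TRUE]
  reference <- matrix(reference, ncol = 3)
  stopifnot(nrow(reference) == n)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("channel axis must have non-zero length")
  structure(list(coords = coords, residue = as.integer(residue),
                 subunit = as.integer(subunit), waters = waters,
                 reference = reference, axis = axis / nrm),
            class = "coord_ensemble")
}

#' @export
print.coord_ensemble <- function(x, ...) {
  cat(sprintf("Coordinate ensemble: %d snapshots, %d residues x %d subunits%s\n",
              dim(x$coords)[1], length(unique(x$residue)),
              length(unique(x$subunit)),
              if (is.null(x$waters)) "" else ", with waters"))
  invisible(x)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping `mobile` onto `fixed`,
#' with the determinant constrained to +1 so mirror images are never
#' produced (a reflected structure retains a documented residual RMSD).
#' The transform is returned explicitly so it can be re-applied to
#' additional coordinates (e.g. waters) rigidly attached to the mobile
#' frame.
#'
#' @param mobile,fixed `N x 3` coordinate matrices, N >= 3 non-collinear
#'   points.
#' @return List with `rotation` (3x3), `center_mobile`, `center_fixed`;
#'   apply with [apply_rigid_transform()].
#' @export
kabsch_transform <- function(mobile, fixed) {
  mobile <- as.matrix(mobile); fixed <- as.matrix(fixed)
  stopifnot(ncol(mobile) == 3L, all(dim(mobile) == dim(fixed)))
  if (nrow(mobile) < 3L) stop("need >= 3 reference points")
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  xm <- sweep(mobile, 2, cm); xf <- sweep(fixed, 2, cf)
  if (qr(xm)$rank < 2L) stop("degenerate (collinear) reference configuration")
  h <- crossprod(xm, xf)                  # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(rotation = rot, center_mobile = cm, center_fixed = cf)
}

#' @rdname kabsch_transform
#' @param x `k x 3` coordinates to transform.
#' @param transform A transform from [kabsch_transform()].
#' @export
apply_rigid_transform <- function(x, transform) {
  x <- matrix(x, ncol = 3)
  sweep(sweep(x, 2, transform$center_mobile) %*% transform$rotation,
        2, transform$center_fixed, "+")
}

#' Superimpose every snapshot onto the reference model
#'
#' Each snapshot is rigidly fitted (minimal Calpha RMSD, proper rotation)
#' onto the ensemble's reference model — the initial structure, fitted
#' once rather than iteratively to the mean. Waters, when present, ride
#' along with their snapshot's transform.
#'
#' @param ensemble A [coord_ensemble()].
#' @return The aligned ensemble; per-snapshot post-fit RMSDs (Angstrom)
#'   in the `"rmsd"` attribute.
#' @export
superimpose <- function(ensemble) {
  stopifnot(inherits(ensemble, "coord_ensemble"))
  m <- dim(ensemble$coords)[1]
  rmsd <- numeric(m)
  for (i in seq_len(m)) {
    snap <- ensemble$coords[i, , ]
    tr <- kabsch_transform(snap, ensemble$reference)
    fitted <- apply_rigid_transform(snap, tr)
    ensemble$coords[i, , ] <- fitted
    rmsd[i] <- sqrt(mean(rowSums((fitted - ensemble$reference)^2)))
    if (!is.null(ensemble$waters) && !is.null(ensemble$waters[[i]]) &&
        nrow(ensemble$waters[[i]]) > 0)
      ensemble$waters[[i]] <- apply_rigid_transform(ensemble$waters[[i]], tr)
  }
  attr(ensemble, "rmsd") <- rmsd
  ensemble
}

#' Root mean square fluctuation per residue
#'
#' `RMSF_n = sqrt( (1/M) sum_m |r_mn - <r_n>|^2 )` evaluated per atom
#' position, then averaged over the equivalent positions of the
#' subunits so one value is reported per residue. The ensemble should be
#' superimposed first ([superimpose()]); set `align = TRUE` to do so
#' here.
#'
#' @param ensemble A [coord_ensemble()].
#' @param align Superimpose onto the reference before computing
#'   (default `FALSE`; generated ensembles are already in frame).
#' @return Object of class `"rmsf_profile"`: data.frame `residue`,
#'   `rmsf` (Angstrom); per-atom values in the `"per_atom"` attribute.
#' @export
rmsf <- function(ensemble, align = FALSE) {
  stopifnot(inherits(ensemble, "coord_ensemble"))
  if (align) ensemble <- superimpose(ensemble)
  co <- ensemble$coords
  mean_pos <- apply(co, c(2, 3), mean)
  dev2 <- sweep(co, c(2, 3), mean_pos)^2
  per_atom <- sqrt(apply(dev2, 2, sum) / dim(co)[1])   # sums over m and xyz
  res <- sort(unique(ensemble$residue))
  prof <- vapply(res, function(r) mean(per_atom[ensemble$residue == r]),
                 numeric(1))
  out <- data.frame(residue = res, rmsf = prof)
  attr(out, "per_atom") <- per_atom
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' Fractional RMSF change between cold and warm ensembles
#'
#' `(RMSF_cold - RMSF_warm) / RMSF_cold` per residue, with residues whose
#' magnitude exceeds the significance band (default 20 percent, the
#' conventional bound for nonspecific thermal effects) flagged.
#' Residues with zero cold RMSF are returned as `NA` and flagged in the
#' `undefined` column.
#'
#' @param cold,warm `"rmsf_profile"` objects over the same residues.
#' @param threshold Significance band half-width (default 0.20).
#' @return data.frame: `residue`, `rmsf_cold`, `rmsf_warm`,
#'   `frac_change`, `significant`, `undefined`.
#' @export
fractional_rmsf_change <- function(cold, warm, threshold = 0.20) {
  stopifnot(identical(cold$residue, warm$residue))
  undef <- cold$rmsf == 0
  frac <- ifelse(undef, NA_real_, (cold$rmsf - warm$rmsf) / cold$rmsf)
  data.frame(residue = cold$residue,
             rmsf_cold = cold$rmsf, rmsf_warm = warm$rmsf,
             frac_change = frac,
             significant = !undef & abs(frac) > threshold,
             undefined = undef)
}

#' Per-residue radial distance to the channel axis
#'
#' For each residue, the mean over snapshots and subunits of the distance
#' from its Calpha to the channel axis, measured in the plane normal to
#' the axis. For a tetramer aligned on z this is the average in-plane
#' distance to the pore centre; its cold-minus-warm change quantifies
#' per-residue contraction (negative: more packed) or expansion.
#'
#' @param ensemble A [coord_ensemble()].
#' @return data.frame `residue`, `radial_rg` (Angstrom).
#' @export
radial_rg <- function(ensemble) {
  stopifnot(inherits(ensemble, "coord_ensemble"))
  a <- ensemble$axis
  co <- ensemble$coords
  m <- dim(co)[1]; n <- dim(co)[2]
  flat <- matrix(aperm(co, c(2, 1, 3)), nrow = m * n, ncol = 3) # atom-major
  proj <- drop(flat %*% a)
  radial <- sqrt(pmax(rowSums(flat^2) - proj^2, 0))
  rad_atom <- rowMeans(matrix(radial, nrow = n, ncol = m))
  res <- sort(unique(ensemble$residue))
  data.frame(residue = res,
             radial_rg = vapply(res, function(r)
               mean(rad_atom[ensemble$residue == r]), numeric(1)))
}

#' @rdname radial_rg
#' @param cold,warm Ensembles at the two temperatures (same residues).
#' @return `delta_radial_rg()`: data.frame `residue`, `delta_rg`
#'   (cold minus warm, Angstrom).
#' @export
delta_radial_rg <- function(cold, warm) {
  rc <- radial_rg(cold); rw <- radial_rg(warm)
  stopifnot(identical(rc$residue, rw$residue))
  data.frame(residue = rc$residue, delta_rg = rc$radial_rg - rw$radial_rg)
}

#' Water molecules contacting each residue
#'
#' Counts water oxygens strictly within `cutoff` of any Calpha copy of a
#' residue (the Calpha stands in for the residue at coarse resolution),
#' averaged over snapshots. The default cutoff of 3.5 Angstrom is the
#' conventional first-hydration-shell bound; a water exactly at the
#' cutoff is excluded.
#'
#' @param ensemble A [coord_ensemble()] carrying waters.
#' @param residues Residue indices to report (default: all).
#' @param cutoff Contact cutoff in Angstrom (default 3.5).
#' @return data.frame `residue`, `n_waters` (mean count per snapshot).
#' @export
count_water_contacts <- function(ensemble, residues = NULL, cutoff = 3.5) {
  stopifnot(inherits(ensemble, "coord_ensemble"))
  res_all <- sort(unique(ensemble$residue))
  if (is.null(residues)) residues <- res_all
  m <- dim(ensemble$coords)[1]
  if (is.null(ensemble$waters) ||
      all(vapply(ensemble$waters, function(w) is.null(w) || nrow(w) == 0,
                 logical(1)))) {
    warning("ensemble carries no water coordinates; all counts are 0")
    return(data.frame(residue = residues, n_waters = 0))
  }
  counts <- matrix(0, nrow = m, ncol = length(residues))
  for (i in seq_len(m)) {
    w <- ensemble$waters[[i]]
    if (is.null(w) || nrow(w) == 0) next
    snap <- matrix(ensemble$coords[i, , ], ncol = 3)
    for (j in seq_along(residues)) {
      ca <- snap[ensemble$residue == residues[j], , drop = FALSE]
      d2 <- outer(rowSums(w^2), rowSums(ca^2), "+") - 2 * w %*% t(ca)
      counts[i, j] <- sum(apply(d2, 1, min) < cutoff^2)
    }
  }
  data.frame(residue = residues, n_waters = colMeans(counts))
}

#' @rdname count_water_contacts
#' @param cold,warm Ensembles at the two temperatures.
#' @return `delta_water_contacts()`: data.frame `residue`,
#'   `delta_waters` (cold minus warm mean counts).
#' @export
delta_water_contacts <- function(cold, warm, residues = NULL, cutoff = 3.5) {
  wc <- count_water_contacts(cold, residues, cutoff)
  ww <- count_water_contacts(warm, residues, cutoff)
  stopifnot(identical(wc$residue, ww$residue))
  data.frame(residue = wc$residue,
             delta_waters = wc$n_waters - ww$n_waters)
}

#' Full per-residue descriptor report for a cold/warm ensemble pair
#'
#' @param cold,warm [coord_ensemble()]s over the same residues.
#' @param cutoff Water-contact cutoff (Angstrom).
#' @param rmsf_threshold Significance band for fractional RMSF change.
#' @param align Superimpose both ensembles first.
#' @return data.frame: `residue`, `rmsf_cold`, `rmsf_warm`,
#'   `frac_change`, `significant`, `radial_rg_delta`, `delta_waters`.
#' @export
ensemble_report <- function(cold, warm, cutoff = 3.5, rmsf_threshold = 0.20,
                            align = FALSE) {
  if (align) { cold <- superimpose(cold); warm <- superimpose(warm) }
  fr <- fractional_rmsf_change(rmsf(cold), rmsf(warm), rmsf_threshold)
  dr <- delta_radial_rg(cold, warm)
  has_waters <- !is.null(cold$waters) || !is.null(warm$waters)
  dw <- if (has_waters) delta_water_contacts(cold, warm, cutoff = cutoff)
        else data.frame(residue = fr$residue, delta_waters = NA_real_)
  data.frame(residue = fr$residue,
             rmsf_cold = fr$rmsf_cold, rmsf_warm = fr$rmsf_warm,
             frac_change = fr$frac_change, significant = fr$significant,
             radial_rg_delta = dr$delta_rg,
             delta_waters = dw$delta_waters)
}
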
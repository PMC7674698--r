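# R-side orchestration of the Monte Carlo transport kernel.

# assemble kernel arguments shared by every frame of a phantom
.transport_context <- function(phantom, coherent = FALSE) {
  mats <- phantom$materials
  if (!"air" %in% names(mats)) mats$air <- material_from_table("air")
  mat_names <- names(mats)
  mu <- .material_mu_tables(mats)
  # material index (0-based) for each label id 0..max
  max_id <- max(phantom$organs$id)
  mat_of_label <- integer(max_id + 1L)
  mat_of_label[1L] <- match("air", mat_names) - 1L
  for (i in seq_len(nrow(phantom$organs)))
    mat_of_label[phantom$organs$id[i] + 1L] <-
      match(phantom$organs$material[i], mat_names) - 1L
  list(mu = mu, mat_of_label = mat_of_label, coherent = coherent,
       dims = dim(phantom$labels))
}

#' Simulate one source-distribution frame
#'
#' Samples decays uniformly within the source compartments (in proportion to
#' the given fractions), transports the emitted photons through the phantom
#' by Woodcock delta tracking, and tallies the energy deposited per organ.
#' Results are normalized per decay (including the photons-per-decay factor
#' of the nuclide, 0.9515 for Tc-99m) and per gram of organ mass, i.e. the
#' per-frame dose-rate coefficients of the dose integral. The relative error
#' is estimated from batch means.
#'
#' @param phantom A `phantom` object.
#' @param source_fractions Named numeric vector of activity fractions by
#'   source organ (e.g. `c(kidney_L = .5, kidney_R = .5)`); must sum to 1.
#'   Zero-fraction compartments are allowed.
#' @param nuclide A `radionuclide` (default [tc99m()]).
#' @param n_histories Number of decays to simulate (>= 1000).
#' @param seed Integer seed for the transport random stream (required: runs
#'   are reproducible by contract).
#' @param n_batches Number of batches for the error estimate (>= 10).
#' @param coherent Transport coherent (Rayleigh) scattering? Default `FALSE`.
#' @param cutoff_kev Energy cutoff; photons below it deposit locally.
#' @return A `dose_rate_map`: data.frame with columns `organ`,
#'   `mev_per_g_per_decay`, `rel_err`; attributes `histories`, `seed`,
#'   `emitted_mev`, `deposited_mev` and `batches` (per-organ batch sums, for
#'   accumulation).
#' @export
simulate_frame <- function(phantom, source_fractions, nuclide = tc99m(),
                           n_histories = 1e5, seed, n_batches = 20,
                           coherent = FALSE, cutoff_kev = 10) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required: transport runs are reproducible by contract")
  if (n_histories < 1e3) stop("n_histories must be >= 1000")
  if (n_batches < 10) stop("need >= 10 batches for the error estimate")
  src <- source_fractions[source_fractions > 0]
  if (length(src) == 0) stop("empty source: all fractions are zero")
  if (abs(sum(source_fractions) - 1) > 1e-9)
    stop("source fractions must sum to 1")
  ctx <- .transport_context(phantom, coherent)
  vox <- lapply(names(src), function(o) .organ_voxels(phantom, o))
  empty <- lengths(vox) == 0
  if (any(empty)) stop("source organ has no voxels: ",
                       paste(names(src)[empty], collapse = ", "))
  lines <- nuclide$lines
  res <- cpp_transport(
    as.integer(phantom$labels), ctx$dims, phantom$voxel_mm,
    ctx$mat_of_label, ctx$mu$energy_kev,
    ctx$mu$photo, ctx$mu$incoh, ctx$mu$coh, ctx$coherent,
    vox, as.numeric(src),
    lines$energy_mev * 1000, lines$yield_pct / sum(lines$yield_pct),
    cutoff_kev, as.integer(n_histories), as.integer(n_batches),
    as.numeric(seed))
  .dose_rate_map(phantom, nuclide, res$edep_mev, n_histories, seed,
                 emitted = res$emitted_mev)
}

# batch matrix (n_batch x n_label) of deposited MeV -> dose_rate_map
.dose_rate_map <- function(phantom, nuclide, edep, n_hist, seed,
                           emitted = NULL) {
  tab <- phantom$organs
  w <- photons_per_decay(nuclide)
  nb <- nrow(edep)
  per_hist <- n_hist / nb                     # histories per batch
  # per-batch MeV/g per decay for each organ
  out <- data.frame(organ = tab$organ,
                    mev_per_g_per_decay = NA_real_, rel_err = NA_real_)
  for (i in seq_len(nrow(tab))) {
    vals <- w * edep[, tab$id[i] + 1L] / per_hist / tab$mass_g[i]
    m <- mean(vals)
    out$mev_per_g_per_decay[i] <- m
    out$rel_err[i] <- if (m > 0)
      stats::sd(vals) / sqrt(nb) / m else NA_real_
  }
  structure(out, class = c("dose_rate_map", "data.frame"),
            histories = n_hist, seed = seed, batches = edep,
            emitted_mev = if (!is.null(emitted)) sum(emitted) else NA_real_,
            emitted_mev_batch = emitted,
            deposited_mev = sum(edep))
}

#' Run transport until target organs reach a relative-error target
#'
#' Adds batches of histories until every organ of interest reaches the
#' requested relative error (the convergence criterion used for the
#' production tallies is 3 percent) or the history budget is exhausted.
#' Non-convergence is reported through the `converged` attribute, not as an
#' error.
#'
#' @inheritParams simulate_frame
#' @param target_rel_err Target relative error in (0, 1).
#' @param organs_of_interest Character vector of organ labels to converge.
#' @param max_histories History budget.
#' @param chunk Histories added per iteration.
#' @return A `dose_rate_map` with attributes `converged` (named logical per
#'   organ of interest) and `histories`.
#' @export
run_until_converged <- function(phantom, source_fractions,
                                nuclide = tc99m(), target_rel_err = 0.03,
                                organs_of_interest = c("kidney_L", "kidney_R"),
                                seed, max_histories = 2e6, chunk = 5e4,
                                coherent = FALSE) {
  stopifnot(target_rel_err > 0, target_rel_err < 1)
  if (missing(seed)) stop("a seed is required")
  total <- 0L
  edep <- NULL
  it <- 0L
  repeat {
    it <- it + 1L
    n <- as.integer(min(chunk, max_histories - total))
    if (n < 1e3) break
    dm <- simulate_frame(phantom, source_fractions, nuclide, n,
                         seed = seed + it, coherent = coherent)
    edep <- rbind(edep, attr(dm, "batches"))
    total <- total + n
    map <- .dose_rate_map(phantom, nuclide, edep, total, seed)
    re <- map$rel_err[match(organs_of_interest, map$organ)]
    if (all(!is.na(re) & re <= target_rel_err) || total >= max_histories)
      break
  }
  re <- map$rel_err[match(organs_of_interest, map$organ)]
  attr(map, "converged") <- stats::setNames(!is.na(re) &
                                            re <= target_rel_err,
                                            organs_of_interest)
  map
}
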
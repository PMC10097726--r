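# Gel-fraction molecular-weight migration QC: proteins crosslinked to other
# proteins ("piggy-back riders") shift above their predicted monomeric mass,
# whereas direct RNA binders migrate in the fraction matching it.

#' Mask gel-fraction detections failing the replicate/peptide rule
#'
#' A (protein, fraction) is kept only when detected with at least
#' `min_peptides` unique peptides in at least `min_replicates` of the
#' replicates; otherwise the whole fraction is masked for that protein.
#'
#' @param fp a [fraction_profile()] (uses its `peptides` array when present).
#' @param min_peptides minimum unique peptides per cell (default 2).
#' @param min_replicates minimum replicates with a valid detection (default 2).
#' @return the filtered [fraction_profile()].
#' @export
filter_fraction_detections <- function(fp, min_peptides = 2L,
                                       min_replicates = 2L) {
  stopifnot(inherits(fp, "fraction_profile"))
  detected <- fp$valid & !is.na(fp$ibaq) & fp$ibaq > 0
  if (!is.null(fp$peptides))
    detected <- detected & !is.na(fp$peptides) & fp$peptides >= min_peptides
  n_rep <- apply(detected, c(1, 3), sum)          # protein x fraction
  pass <- n_rep >= min_replicates
  keep <- aperm(array(pass, dim(fp$ibaq)[c(1, 3, 2)]), c(1, 3, 2))
  valid <- fp$valid & detected & keep
  ibaq <- fp$ibaq
  ibaq[!valid] <- NA_real_
  fraction_profile(ibaq, fp$predicted_mass_kda, bounds_kda = fp$bounds_kda,
                   valid = valid, peptides = fp$peptides)
}

#' Per-cell iBAQ proportions and per-fraction profiles
#'
#' Each valid iBAQ value is divided by the sum of all valid iBAQ values for
#' that protein across every (replicate, fraction) cell; the per-fraction
#' profile is the sum of the proportions over replicates, so the profile of
#' each retained protein sums to 1.
#'
#' @param fp a (filtered) [fraction_profile()].
#' @return list: `per_cell` (3-d proportion array), `profile` (protein x
#'   fraction matrix), `dropped` (proteins with zero total valid iBAQ,
#'   removed with a `message()`).
#' @export
fraction_proportions <- function(fp) {
  stopifnot(inherits(fp, "fraction_profile"))
  x <- fp$ibaq
  x[!fp$valid] <- NA_real_
  total <- apply(x, 1, sum, na.rm = TRUE)
  dropped <- dimnames(x)[[1]][total <= 0]
  if (length(dropped) > 0L)
    message(length(dropped), " protein(s) dropped with zero total valid iBAQ")
  keep <- total > 0
  x <- x[keep, , , drop = FALSE]
  per_cell <- sweep(x, 1, total[keep], "/")
  profile <- apply(per_cell, c(1, 3), sum, na.rm = TRUE)
  list(per_cell = per_cell, profile = profile, dropped = dropped)
}

#' Pooled weighted density of observed molecular weights
#'
#' Pools the per-protein fraction proportions as weights on the fraction mass
#' intervals; the pooled weights integrate (sum) to the number of proteins.
#'
#' @param profile protein x fraction proportion matrix.
#' @param bounds_kda fraction upper bounds.
#' @return data.frame `fraction_index`, `lower_kda`, `upper_kda`, `weight`
#'   (pooled), `density` (weight per kDa; `NA` for the unbounded fraction).
#' @export
weighted_mass_density <- function(profile, bounds_kda = default_fraction_bounds()) {
  stopifnot(is.matrix(profile), ncol(profile) == length(bounds_kda))
  lower <- c(0, bounds_kda[-length(bounds_kda)])
  weight <- colSums(profile, na.rm = TRUE)
  width <- bounds_kda - lower
  data.frame(fraction_index = seq_along(bounds_kda), lower_kda = lower,
             upper_kda = bounds_kda, weight = weight,
             density = ifelse(is.finite(width), weight / width, NA_real_))
}

# local maxima of a profile over ordered fractions; plateaus collapse to
# their lowest-mass index
.local_maxima <- function(p) {
  n <- length(p)
  if (n == 1L) return(if (p[1] > 0) 1L else integer(0))
  ext <- c(-Inf, p, -Inf)
  out <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && p[j + 1L] == p[i]) j <- j + 1L   # plateau [i, j]
    if (p[i] > 0 && ext[i] < p[i] && ext[j + 2L] < p[i])
      out <- c(out, i)
    i <- j + 1L
  }
  out
}

#' Classify the gel migration of one protein
#'
#' `monomeric`: the modal fraction contains the predicted monomeric mass.
#' `boundary_proximal`: the modal fraction is the next one up and the
#' predicted mass lies within `boundary_kda` below its fraction boundary
#' (gel resolution cannot separate it). `bimodal`: at least two local maxima,
#' each holding at least `bimodal_tau` of the mass, separated by at least one
#' fraction, one of them at the predicted (or boundary) fraction. `shifted`:
#' the mode is above the predicted fraction otherwise - the piggy-back
#' signature. `unclassified`: mode below the predicted fraction or missing
#' predicted mass.
#'
#' @param profile numeric proportion vector over the ordered fractions.
#' @param predicted_mass_kda predicted monomeric mass.
#' @param bounds_kda fraction upper bounds.
#' @param boundary_kda boundary-proximity rule (default 10 kDa).
#' @param bimodal_tau minimum share of each bimodal peak (default 0.25).
#' @return list of class `migration_call`: `predicted_fraction`,
#'   `modal_fraction`, `call`, `higher_mass_fraction_share`, `near_boundary`.
#' @export
classify_migration <- function(profile, predicted_mass_kda,
                               bounds_kda = default_fraction_bounds(),
                               boundary_kda = 10, bimodal_tau = 0.25) {
  stopifnot(length(profile) == length(bounds_kda))
  profile[is.na(profile)] <- 0
  if (is.na(predicted_mass_kda)) {
    warning("predicted mass missing; migration unclassified")
    return(structure(list(predicted_fraction = NA_integer_,
                          modal_fraction = NA_integer_, call = "unclassified",
                          higher_mass_fraction_share = NA_real_,
                          near_boundary = NA),
                     class = "migration_call"))
  }
  pf <- which(predicted_mass_kda <= bounds_kda)[1]
  modal <- which.max(profile)                      # lowest index on ties
  near_boundary <- is.finite(bounds_kda[pf]) &&
    (bounds_kda[pf] - predicted_mass_kda) <= boundary_kda
  maxima <- .local_maxima(profile)
  big <- maxima[profile[maxima] >= bimodal_tau]
  bimodal <- length(big) >= 2L &&
    any(diff(sort(big)) >= 2L) &&
    any(big == pf | (near_boundary & big == pf + 1L))
  call <- if (modal == pf) "monomeric"
    else if (modal == pf + 1L && near_boundary) "boundary_proximal"
    else if (bimodal) "bimodal"
    else if (modal > pf) "shifted"
    else "unclassified"
  share <- sum(profile[seq_along(profile) > pf]) / max(sum(profile), 1e-300)
  structure(list(predicted_fraction = pf, modal_fraction = modal, call = call,
                 higher_mass_fraction_share = share,
                 near_boundary = near_boundary),
            class = "migration_call")
}

#' Classify migration for every protein of a profile matrix
#'
#' @param profile protein x fraction proportion matrix (from
#'   [fraction_proportions()]).
#' @param predicted_mass_kda named numeric per protein.
#' @param bounds_kda,boundary_kda,bimodal_tau see [classify_migration()].
#' @return data.frame: `protein`, `predicted_mass_kda`, `predicted_fraction`,
#'   `modal_fraction`, `call`, `higher_mass_fraction_share`, `near_boundary`.
#' @export
classify_migration_all <- function(profile, predicted_mass_kda,
                                   bounds_kda = default_fraction_bounds(),
                                   boundary_kda = 10, bimodal_tau = 0.25) {
  proteins <- rownames(profile)
  calls <- lapply(proteins, function(p)
    classify_migration(profile[p, ], predicted_mass_kda[[p]], bounds_kda,
                       boundary_kda, bimodal_tau))
  data.frame(protein = proteins,
             predicted_mass_kda = unname(predicted_mass_kda[proteins]),
             predicted_fraction = vapply(calls, `[[`, integer(1),
                                         "predicted_fraction"),
             modal_fraction = vapply(calls, `[[`, integer(1), "modal_fraction"),
             call = vapply(calls, `[[`, character(1), "call"),
             higher_mass_fraction_share =
               vapply(calls, `[[`, numeric(1), "higher_mass_fraction_share"),
             near_boundary = vapply(calls, `[[`, logical(1), "near_boundary"),
             stringsAsFactors = FALSE)
}

#' Piggy-back risk summary over migration calls
#'
#' Among proteins that preferentially localize to fractions above their
#' predicted mass (higher-mass share > 0.5): the percentage that are both
#' capture hits and boundary-proximal (predicted mass within `boundary_kda`
#' below a fraction boundary) - the sub-population whose apparent shift is
#' explained by gel resolution rather than protein-protein crosslinking.
#'
#' @param calls data.frame from [classify_migration_all()].
#' @param hit_set character vector of capture hits.
#' @param share_threshold higher-mass share defining preferential
#'   localization (default 0.5).
#' @return list: `n_shifted_preferential`, `n_hit_near_boundary`,
#'   `pct_hit_near_boundary` (`NA` when the shifted set is empty),
#'   `class_counts` (table of calls).
#' @export
piggyback_summary <- function(calls, hit_set, share_threshold = 0.5) {
  shifted <- calls[!is.na(calls$higher_mass_fraction_share) &
                     calls$higher_mass_fraction_share > share_threshold, ,
                   drop = FALSE]
  n <- nrow(shifted)
  n_risk <- sum(shifted$protein %in% hit_set & shifted$near_boundary)
  list(n_shifted_preferential = n,
       n_hit_near_boundary = n_risk,
       pct_hit_near_boundary = if (n == 0L) NA_real_ else 100 * n_risk / n,
       class_counts = table(calls$call))
}
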
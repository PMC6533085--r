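# Docked-vesicle and active-zone morphometry from electron-micrograph
# measurements. Vesicle positions are distances (nm) from the active-zone
# cytomatrix, the reference point at 0 nm; vesicles within 50 nm are
# considered docked.

#' Morphometric profile of one synaptic bouton
#'
#' @param synapse_id identifier string.
#' @param az_length active-zone length, nm (> 0).
#' @param vesicle_distances numeric vector of vesicle distances from the
#'   active-zone cytomatrix, nm (all >= 0; may be empty).
#' @param genotype `"WT"` or `"KO"`.
#' @return An object of class `synapse_profile`.
#' @export
synapse_profile <- function(synapse_id, az_length, vesicle_distances = numeric(0),
                            genotype = "WT") {
  check_scalar(az_length, "az_length", lower = .Machine$double.xmin)
  if (length(vesicle_distances) && any(!is.finite(vesicle_distances) |
                                       vesicle_distances < 0)) {
    stop("vesicle distances must be finite and >= 0", call. = FALSE)
  }
  structure(list(synapse_id = as.character(synapse_id),
                 az_length = az_length,
                 vesicle_distances = as.numeric(vesicle_distances),
                 genotype = genotype),
            class = "synapse_profile")
}

#' Count docked vesicles
#'
#' Number of vesicles within `cutoff` nm of the active-zone cytomatrix.
#' The boundary is inclusive (a vesicle at exactly the cutoff counts as
#' docked), consistently with the first histogram bin of
#' [bin_vesicle_distances()].
#'
#' @param profile a [synapse_profile()].
#' @param cutoff docking cutoff, nm (default 50).
#' @return integer count.
#' @examples
#' p <- synapse_profile("s1", 500, c(10, 49, 51, 120))
#' count_docked(p)
#' @export
count_docked <- function(profile, cutoff = 50) {
  stopifnot(inherits(profile, "synapse_profile"))
  check_scalar(cutoff, "cutoff", lower = .Machine$double.xmin)
  sum(profile$vesicle_distances <= cutoff)
}

#' Histogram of vesicle distances from the active zone
#'
#' Bins vesicle distances in `bin_width`-nm bins starting at the
#' active-zone cytomatrix (0 nm). The first bin is closed at the docking
#' cutoff (`[0, bin_width]`) so that it always equals [count_docked()] with
#' `cutoff = bin_width`; subsequent bins are `(k*w, (k+1)*w]`. The
#' histogram sums to the total vesicle count.
#'
#' @param profile a [synapse_profile()].
#' @param bin_width bin width, nm (default 50).
#' @return integer vector of bin counts (empty profile gives a single 0).
#' @export
bin_vesicle_distances <- function(profile, bin_width = 50) {
  stopifnot(inherits(profile, "synapse_profile"))
  check_scalar(bin_width, "bin_width", lower = .Machine$double.xmin)
  d <- profile$vesicle_distances
  if (!length(d)) return(0L)
  bin <- pmax(1L, as.integer(ceiling(d / bin_width)))
  tabulate(bin, nbins = max(bin))
}

#' Correlation between active-zone length and docked-vesicle count
#'
#' Pearson correlation (with two-sided p-value) of active-zone length
#' against the docked-vesicle count across boutons.
#'
#' @param profiles list of [synapse_profile()]s (>= 3, non-degenerate
#'   variance in both variables).
#' @param cutoff docking cutoff passed to [count_docked()].
#' @return list with `r`, `p` and `n`.
#' @export
az_docked_correlation <- function(profiles, cutoff = 50) {
  if (!length(profiles) ||
      !all(vapply(profiles, inherits, TRUE, "synapse_profile"))) {
    stop("'profiles' must be a list of synapse_profile objects", call. = FALSE)
  }
  az <- vapply(profiles, `[[`, 0, "az_length")
  docked <- vapply(profiles, count_docked, 0L, cutoff = cutoff)
  if (length(az) < 3L) stop("need at least 3 profiles", call. = FALSE)
  if (stats::sd(az) == 0 || stats::sd(docked) == 0) {
    stop("degenerate variance in AZ length or docked count", call. = FALSE)
  }
  ct <- stats::cor.test(az, as.numeric(docked), method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(az))
}

#' Generate a synthetic morphometry cohort
#'
#' Samples bouton profiles with a planted positive correlation between
#' active-zone length and docked-vesicle count: AZ lengths are
#' gamma-distributed (wild-type mean about 520 nm) and the docked count is
#' Poisson with mean proportional to AZ length. The knockout mode shortens
#' the AZ-length distribution and truncates its long tail (no AZ above
#' 800 nm), removing the large-bouton/high-count end of the joint
#' distribution. Non-docked vesicles are placed between 50 and 400 nm.
#'
#' @param n_synapses number of boutons (>= 1).
#' @param genotype `"WT"` or `"KO"`.
#' @param seed integer seed.
#' @return list of [synapse_profile()]s.
#' @export
make_morphometry_fixture <- function(n_synapses, genotype = c("WT", "KO"),
                                     seed = 1) {
  check_scalar(n_synapses, "n_synapses", lower = 1, integer = TRUE)
  genotype <- match.arg(genotype)
  check_scalar(seed, "seed", integer = TRUE)
  with_seed(seed, {
    lapply(seq_len(n_synapses), function(i) {
      if (genotype == "WT") {
        az <- stats::rgamma(1, shape = 11, scale = 47)
      } else {
        az <- stats::rgamma(1, shape = 11, scale = 40)
        while (az > 800) az <- stats::rgamma(1, shape = 11, scale = 40)
      }
      az <- max(az, 50)
      n_docked <- stats::rpois(1, az / 75)
      n_far <- stats::rpois(1, 2 * n_docked + 8)
      d <- c(stats::runif(n_docked, 0, 50), stats::runif(n_far, 50.001, 400))
      synapse_profile(sprintf("%s_bouton%04d", tolower(genotype), i),
                      az_length = az, vesicle_distances = d,
                      genotype = genotype)
    })
  })
}
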
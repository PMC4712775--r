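#' Configuration for the two-hit temporal-order simulator
#'
#' The simulator grows one organism as a binary cell-lineage tree of
#' `divisions` synchronous divisions, with no cell death or selection (the
#' simplest model consistent with the temporal-order argument). The
#' `nCompartments` subtrees rooted at level `log2(nCompartments)` represent
#' organ sites at risk. At every division each daughter cell independently
#' acquires a hotspot missense hit with probability `muHotspot` and any
#' loss-of-function hit (nonsense SNV, frameshift, splice disruption,
#' allele loss, aggregated) with probability `muLof`. A cell that completes
#' both hits founds a tumorigenic clade: one founding event is one disease
#' focus, and the clade is not expanded further.
#'
#' Scenarios: `germline_lof` starts the zygote LOF-positive;
#' `mosaic_hotspot` / `mosaic_lof` force the first hit into one cell at
#' division `mosaicOnsetDivision`; `sporadic` requires both hits to arise
#' spontaneously in one lineage.
#'
#' Absolute rates are user parameters labelled illustrative -- only the
#' LOF-to-hotspot *ratio* is anchored, defaulting to the
#' `lofToHotspotRatio` of the packaged transcript's [targetSizeReport()]
#' when neither `muLof` nor `lofHotspotRatio` is supplied.
#'
#' @param scenario one of `"germline_lof"`, `"mosaic_lof"`,
#'   `"mosaic_hotspot"`, `"sporadic"`.
#' @param nCompartments number of organ compartments (a power of two).
#' @param divisions binary divisions per lineage from zygote to terminal
#'   cells.
#' @param muHotspot per-division, per-daughter probability of a hotspot
#'   missense hit.
#' @param muLof per-division probability of any LOF hit; defaults to
#'   `muHotspot * lofHotspotRatio`.
#' @param lofHotspotRatio ratio used when `muLof` is NULL; defaults to the
#'   packaged transcript's target-size ratio.
#' @param mosaicOnsetDivision division at which the mosaic first hit is
#'   forced (mosaic scenarios only); must not exceed `divisions`.
#' @param seed integer seed for the replicate stream.
#' @return a list of class `"SimConfig"`.
#' @export
simConfig <- function(scenario, nCompartments = 8L, divisions = 18L,
                      muHotspot = 1e-6, muLof = NULL,
                      lofHotspotRatio = NULL, mosaicOnsetDivision = 4L,
                      seed = 1L) {
  scenario <- match.arg(scenario, c("germline_lof", "mosaic_lof",
                                    "mosaic_hotspot", "sporadic"))
  k <- as.integer(round(log2(nCompartments)))
  if (2^k != nCompartments)
    stop("nCompartments must be a power of two")
  if (k > divisions) stop("more compartments than lineage divisions allow")
  if (is.null(muLof)) {
    if (is.null(lofHotspotRatio))
      lofHotspotRatio <- targetSizeReport(dicer1Transcript())@lofToHotspotRatio
    muLof <- muHotspot * lofHotspotRatio
  }
  stopifnot(muHotspot >= 0, muHotspot <= 1, muLof >= 0, muLof <= 1)
  if (scenario %in% c("mosaic_hotspot", "mosaic_lof") &&
      mosaicOnsetDivision > divisions)
    stop("mosaicOnsetDivision exceeds divisions")
  structure(list(scenario = scenario,
                 nCompartments = as.integer(nCompartments),
                 divisions = as.integer(divisions),
                 muHotspot = muHotspot, muLof = muLof,
                 mosaicOnsetDivision = as.integer(mosaicOnsetDivision),
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# one organism: returns list(fociPerCompartment, firstOnset)
.simOrganism <- function(cfg) {
  k <- as.integer(round(log2(cfg$nCompartments)))
  D <- cfg$divisions
  muH <- cfg$muHotspot; muL <- cfg$muLof
  d_onset <- if (cfg$scenario %in% c("mosaic_hotspot", "mosaic_lof"))
    cfg$mosaicOnsetDivision else NA_integer_
  first_hit <- switch(cfg$scenario, mosaic_hotspot = "H", mosaic_lof = "L",
                      NA_character_)

  foci <- integer(cfg$nCompartments)
  first_onset <- NA_integer_

  record_focus <- function(comp, level) {
    foci[comp] <<- foci[comp] + 1L
    if (is.na(first_onset) || level < first_onset) first_onset <<- level
  }

  # phase 1: explicit cells from the zygote down to the compartment founders
  states <- if (cfg$scenario == "germline_lof") "L" else "0"
  if (k > 0L) {
    for (lev in seq_len(k)) {
      parent <- rep(states, each = 2L)
      n_d <- length(parent)
      gainH <- stats::runif(n_d) < muH
      gainL <- stats::runif(n_d) < muL
      if (identical(lev, d_onset) && !is.na(first_hit)) {
        pick <- sample.int(n_d, 1L)
        if (first_hit == "H") gainH[pick] <- TRUE else gainL[pick] <- TRUE
      }
      daughters <- parent
      for (i in seq_len(n_d)) {
        hasH <- parent[i] %in% c("H") || gainH[i]
        hasL <- parent[i] %in% c("L") || gainL[i]
        if (parent[i] == "X") { daughters[i] <- "X"; next }
        if (hasH && hasL) {
          # compartment attribution for a pre-compartment focus: leftmost
          # descendant compartment (early double hits are vanishingly rare)
          comp <- (i - 1L) * 2L^(k - lev) + 1L
          record_focus(comp, lev)
          daughters[i] <- "X"
        } else daughters[i] <- if (hasH) "H" else if (hasL) "L" else "0"
      }
      states <- daughters
    }
  }

  onset_comp <- NA_integer_
  if (!is.na(d_onset) && d_onset > k) onset_comp <- sample.int(cfg$nCompartments, 1L)

  # phase 2: aggregate counts per compartment from level k to D
  pboth <- muH * muL
  pH <- muH * (1 - muL)
  pL <- muL * (1 - muH)
  for (comp in seq_len(cfg$nCompartments)) {
    st <- states[comp]
    if (st == "X") next
    n0 <- as.numeric(st == "0"); nH <- as.numeric(st == "H")
    nL <- as.numeric(st == "L")
    if (k < D) for (lev in seq.int(k + 1L, D)) {
      d0 <- 2 * n0; dH <- 2 * nH; dL <- 2 * nL
      nboth <- if (d0 > 0 && pboth > 0) stats::rbinom(1L, d0, pboth) else 0L
      nh_new <- if (d0 - nboth > 0 && pH > 0)
        stats::rbinom(1L, d0 - nboth, pH / (1 - pboth)) else 0L
      nl_new <- if (d0 - nboth - nh_new > 0 && pL > 0)
        stats::rbinom(1L, d0 - nboth - nh_new, pL / (1 - pboth - pH)) else 0L
      gainL_H <- if (dH > 0 && muL > 0) stats::rbinom(1L, dH, muL) else 0L
      gainH_L <- if (dL > 0 && muH > 0) stats::rbinom(1L, dL, muH) else 0L

      n_new_foci <- nboth + gainL_H + gainH_L
      if (n_new_foci > 0) {
        foci[comp] <- foci[comp] + n_new_foci
        if (is.na(first_onset) || lev < first_onset) first_onset <- lev
      }
      n0 <- d0 - nboth - nh_new - nl_new
      nH <- dH - gainL_H + nh_new
      nL <- dL - gainH_L + nl_new
      if (!is.na(onset_comp) && comp == onset_comp && lev == d_onset) {
        if (n0 > 0) {
          n0 <- n0 - 1
          if (first_hit == "H") nH <- nH + 1 else nL <- nL + 1
        } else if (first_hit == "H" && nL > 0) {
          # the struck cell already carried a LOF hit: immediate focus
          nL <- nL - 1
          foci[comp] <- foci[comp] + 1L
          if (is.na(first_onset) || lev < first_onset) first_onset <- lev
        } else if (first_hit == "L" && nH > 0) {
          nH <- nH - 1
          foci[comp] <- foci[comp] + 1L
          if (is.na(first_onset) || lev < first_onset) first_onset <- lev
        }
      }
    }
  }
  list(foci = foci, firstOnset = first_onset)
}

#' Run the two-hit simulator
#'
#' Simulates `nReps` independent organisms under one configuration.
#' Identical configuration and seed give identical outcomes.
#'
#' @param config a [simConfig()].
#' @param nReps number of replicate organisms.
#' @return list with `replicates` (data.frame: `rep`, `fociCount`,
#'   `firstOnsetDivision`, NA when no focus arose), `perCompartment`
#'   (nReps x nCompartments matrix of focus counts) and `config`.
#' @examples
#' cfg <- simConfig("mosaic_hotspot", muHotspot = 1e-5, lofHotspotRatio = 100,
#'                  divisions = 12, seed = 7)
#' sim <- simulateTwoHit(cfg, nReps = 50)
#' mean(sim$replicates$fociCount)
#' @export
simulateTwoHit <- function(config, nReps = 1000L) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  per_comp <- matrix(0L, nrow = nReps, ncol = config$nCompartments)
  foci <- integer(nReps); onset <- rep(NA_integer_, nReps)
  for (r in seq_len(nReps)) {
    res <- .simOrganism(config)
    per_comp[r, ] <- res$foci
    foci[r] <- sum(res$foci)
    onset[r] <- res$firstOnset
  }
  list(replicates = data.frame(rep = seq_len(nReps), fociCount = foci,
                               firstOnsetDivision = onset),
       perCompartment = per_comp,
       config = config)
}

#' Compare simulator scenarios
#'
#' Runs each configuration and reports mean/median focus counts and onset
#' divisions with bootstrap confidence intervals, plus one-sided
#' Mann-Whitney tests of whether the first scenario of each pair yields
#' more foci than the second. All numeric outputs are illustrative model
#' quantities, not clinical estimates.
#'
#' @param configs named list of [simConfig()] objects.
#' @param nReps replicates per scenario.
#' @param bootReps bootstrap resamples for the interval on the mean.
#' @param conf confidence level.
#' @return list with `summary` (one row per scenario) and `tests`
#'   (data.frame of ordered pairs with one-sided p-values).
#' @export
compareScenarios <- function(configs, nReps = 1000L, bootReps = 200L,
                             conf = 0.95) {
  if (is.null(names(configs)))
    names(configs) <- vapply(configs, function(c) c$scenario, "")
  sims <- lapply(configs, simulateTwoHit, nReps = nReps)
  boot_ci <- function(x) {
    means <- vapply(seq_len(bootReps), function(i)
      mean(x[sample.int(length(x), replace = TRUE)]), 1)
    stats::quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  }
  summary_df <- do.call(rbind, lapply(names(sims), function(nm) {
    fc <- sims[[nm]]$replicates$fociCount
    on <- sims[[nm]]$replicates$firstOnsetDivision
    ci <- boot_ci(fc)
    data.frame(scenario = nm, meanFoci = mean(fc), medianFoci = stats::median(fc),
               fociCiLo = ci[1L], fociCiHi = ci[2L],
               meanOnset = if (all(is.na(on))) NA_real_ else mean(on, na.rm = TRUE),
               medianOnset = if (all(is.na(on))) NA_real_ else
                 stats::median(on, na.rm = TRUE),
               pFociPositive = mean(fc > 0),
               stringsAsFactors = FALSE)
  }))
  pairs <- expand.grid(a = names(sims), b = names(sims),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  pairs$p_greater <- vapply(seq_len(nrow(pairs)), function(i) {
    suppressWarnings(stats::wilcox.test(
      sims[[pairs$a[i]]]$replicates$fociCount,
      sims[[pairs$b[i]]]$replicates$fociCount,
      alternative = "greater", exact = FALSE)$p.value)
  }, 1)
  rownames(pairs) <- NULL
  list(summary = summary_df, tests = pairs, sims = sims)
}
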
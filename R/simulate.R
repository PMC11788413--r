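#' Define a synthetic community-assembly scenario
#'
#' A scenario fixes the study design (regions x sites x quadrats along
#' east-west transects), the read depth, and the ecological process that
#' assembles communities, so that downstream inference can be tested
#' against a known truth. The default design mirrors a three-region steppe
#' transect survey: 3 regions x 10 sites x 4 quadrats = 120 samples with
#' at least 80 km between adjacent sites.
#'
#' Processes:
#' \describe{
#'   \item{neutral_drift}{all samples draw from a shared lognormal
#'     regional-abundance vector perturbed by independent per-sample drift
#'     noise; compositional differences are sampling noise plus drift.}
#'   \item{variable_selection}{a Brownian-motion trait on the tree is
#'     matched against a standardized selective environmental variable that
#'     varies across samples; log-weights are penalized by
#'     \code{-strength * (trait - env)^2}. Selection acts on a per-sample
#'     colonization lottery (sd `lottery_sd`, scaled by
#'     `strength / (1 + strength)`): the environment picks the clade,
#'     priority effects pick which clade members dominate at each site.}
#'   \item{homogeneous_selection}{same penalty and lottery, but the
#'     selective optimum is constant across all samples (one standard
#'     deviation above the gradient mean, favouring one conserved clade).}
#'   \item{dispersal_limitation}{taxon weights are multiplied by a spatial
#'     Gaussian kernel centred on a random "home" site, with kernel scale
#'     shrinking as \code{strength} grows.}
#'   \item{homogenizing_dispersal}{per-sample drift noise is shrunk by
#'     \code{1/(1 + strength)}, pulling all samples toward one pooled
#'     regional weight vector.}
#'   \item{mixed}{one process per region (selection, dispersal limitation,
#'     homogenizing dispersal cycled), emulating region-dependent assembly.}
#' }
#'
#' `strength = 0` reduces every process to `neutral_drift`; the constructor
#' enforces this by relabeling.
#'
#' @param process one of the process labels above.
#' @param strength non-negative selection intensity / dispersal scale.
#' @param n_taxa number of taxa (ASVs) in the regional pool.
#' @param tree_tips number of tips of the simulated reference phylogeny
#'   (default `n_taxa`). When larger, the pool is a uniformly random
#'   `n_taxa`-subset of the tips: the tree then represents the broader
#'   clade diversity from which the regional pool is drawn, and the
#'   betaNTI taxa-shuffle null randomizes across all of it.
#' @param n_regions,sites_per_region,quadrats_per_site study design.
#' @param reads_per_sample sequencing depth per sample (default 2000 so the
#'   conventional rarefaction to 800 is always possible).
#' @param trait_conservatism in `[0, 1]`: 1 = fully Brownian (phylogenetically
#'   conserved) environmental optima, 0 = optima independent of the tree.
#' @param env_noise non-negative multiplier on environmental noise around
#'   the longitude gradient (0 makes env variables exactly linear in
#'   longitude).
#' @param selective_var name of the metadata variable that drives selection.
#' @param base_sd standard deviation of the shared lognormal abundance
#'   term on the log scale (heavy-tailed species-abundance distributions
#'   have sd around 2, producing realistic partial occupancy).
#' @param drift_sd standard deviation of the per-sample drift noise on
#'   log-weights.
#' @param lottery_sd standard deviation of the colonization-lottery noise
#'   applied under the selection processes (see above).
#' @param seed integer seed; the whole scenario is deterministic given it.
#' @return an `assembly_scenario` list.
#' @export
assembly_scenario <- function(process = c("neutral_drift", "variable_selection",
                                          "homogeneous_selection",
                                          "dispersal_limitation",
                                          "homogenizing_dispersal", "mixed"),
                              strength = 1,
                              n_taxa = 200,
                              tree_tips = NULL,
                              n_regions = 3,
                              sites_per_region = 10,
                              quadrats_per_site = 4,
                              reads_per_sample = 2000,
                              trait_conservatism = 1,
                              env_noise = 1,
                              selective_var = "MAT",
                              base_sd = 2,
                              drift_sd = 0.3,
                              lottery_sd = 2.5,
                              seed = 1) {
  process <- match.arg(process)
  if (strength < 0) stop_validation("strength must be >= 0")
  if (n_taxa < 2) stop_validation("n_taxa must be >= 2")
  if (trait_conservatism < 0 || trait_conservatism > 1)
    stop_validation("trait_conservatism must be in [0, 1]")
  if (reads_per_sample < 1) stop_validation("reads_per_sample must be >= 1")
  if (strength == 0 && process != "neutral_drift") process <- "neutral_drift"
  tree_tips <- tree_tips %||% n_taxa
  if (tree_tips < n_taxa) stop_validation("tree_tips must be >= n_taxa")
  structure(list(process = process, strength = strength, n_taxa = n_taxa,
                 tree_tips = tree_tips,
                 n_regions = n_regions, sites_per_region = sites_per_region,
                 quadrats_per_site = quadrats_per_site,
                 reads_per_sample = reads_per_sample,
                 trait_conservatism = trait_conservatism,
                 env_noise = env_noise, selective_var = selective_var,
                 base_sd = base_sd, drift_sd = drift_sd,
                 lottery_sd = lottery_sd, seed = as.integer(seed)),
            class = "assembly_scenario")
}

#' @export
print.assembly_scenario <- function(x, ...) {
  cat("assembly_scenario:", x$process, "(strength", x$strength, ")\n")
  cat(" design:", x$n_regions, "regions x", x$sites_per_region, "sites x",
      x$quadrats_per_site, "quadrats;", x$n_taxa, "taxa;",
      x$reads_per_sample, "reads/sample; seed", x$seed, "\n")
  invisible(x)
}

#' Simulate a rooted phylogeny of ASVs
#'
#' Pure-birth (Yule) topology with coalescent-style branch lengths when
#' `ultrametric = TRUE`, otherwise random branch lengths; tips are labeled
#' `ASV_1 .. ASV_n`. Deterministic given `seed`.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed.
#' @param ultrametric if TRUE all root-to-tip path lengths are equal.
#' @return a `phylo` tree with strictly positive branch lengths.
#' @export
simulate_tree <- function(n_taxa, seed = 1, ultrametric = FALSE) {
  if (n_taxa < 2) stop_validation("n_taxa must be >= 2")
  tree <- with_seed(seed, {
    tr <- if (ultrametric) ape::rphylo(n_taxa, birth = 1, death = 0)
          else ape::rtree(n_taxa)
    tr$edge.length <- pmax(tr$edge.length, 1e-6)
    tr
  })
  tree$tip.label <- paste0("ASV_", seq_len(n_taxa))
  validate_tree(tree)
}

# Region templates patterned on arid/semi-arid steppe transects:
# reference latitude, starting longitude, and mean env levels (MAT degC,
# MAP mm, AI, pH).
region_templates <- function(n_regions) {
  base <- data.frame(
    region = c("LP", "IMG", "QTP"),
    lat = c(36.5, 44.3, 32.0),
    lon0 = c(105.0, 112.3, 80.2),
    MAT = c(9.13, 2.52, -3.02),
    MAP = c(466.05, 313.34, 428.84),
    AI = c(0.31, 0.22, 0.30),
    pH = c(8.06, 7.96, 7.81),
    stringsAsFactors = FALSE)
  if (n_regions <= 3L) return(base[seq_len(n_regions), , drop = FALSE])
  extra <- base[rep(seq_len(3L), length.out = n_regions - 3L), , drop = FALSE]
  extra$region <- paste0("R", 4:n_regions)
  extra$lat <- extra$lat + seq_len(nrow(extra)) * 2
  rbind(base, extra)
}

#' Simulate transect-structured sample metadata
#'
#' Lays regions out as east-west transects with inter-site great-circle
#' spacing of at least 80 km, jitters quadrat coordinates by at most
#' 0.001 degrees around their site, and generates environmental variables
#' (MAT, MAP, AI, pH) as linear functions of longitude plus noise, with
#' region-specific means matching typical steppe-transect climatologies.
#'
#' @param scenario an [assembly_scenario()].
#' @return a `sample_metadata` frame with
#'   `n_regions * sites_per_region * quadrats_per_site` rows.
#' @export
simulate_metadata <- function(scenario) {
  stopifnot(inherits(scenario, "assembly_scenario"))
  tmpl <- region_templates(scenario$n_regions)
  # env gradients per degree longitude (east = warmer/wetter on these
  # transects); steppe type follows the aridity tercile within a region
  grad <- c(MAT = 0.35, MAP = 18, AI = 0.009, pH = -0.02)
  noise_sd <- c(MAT = 0.4, MAP = 15, AI = 0.008, pH = 0.08) * scenario$env_noise
  with_seed(scenario$seed + 1L, {
    rows <- list()
    for (r in seq_len(scenario$n_regions)) {
      lat <- tmpl$lat[r]
      # site spacing with 25% margin over the 80 km floor
      spacing_deg <- 80 / (111.195 * cos(lat * pi / 180)) * 1.25
      site_lons <- tmpl$lon0[r] + (seq_len(scenario$sites_per_region) - 1) * spacing_deg
      mid_lon <- mean(site_lons)
      for (s in seq_len(scenario$sites_per_region)) {
        for (q in seq_len(scenario$quadrats_per_site)) {
          lon_q <- site_lons[s] + stats::runif(1, -0.001, 0.001)
          lat_q <- lat + stats::runif(1, -0.001, 0.001)
          env <- vapply(names(grad), function(v)
            tmpl[[v]][r] + grad[[v]] * (site_lons[s] - mid_lon) +
              stats::rnorm(1, 0, noise_sd[[v]]), numeric(1))
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sprintf("%s_S%02d_Q%d", tmpl$region[r], s, q),
            region = tmpl$region[r], steppe = NA_character_,
            site_id = sprintf("%s_S%02d", tmpl$region[r], s),
            latitude = lat_q, longitude = lon_q,
            MAT = env[["MAT"]], MAP = env[["MAP"]],
            AI = env[["AI"]], pH = env[["pH"]],
            stringsAsFactors = FALSE)
        }
      }
    }
    df <- do.call(rbind, rows)
    # steppe category from the within-region aridity tercile:
    # driest third = desert, middle = typical, wettest = meadow
    for (reg in unique(df$region)) {
      i <- df$region == reg
      terc <- cut(rank(df$AI[i], ties.method = "first"),
                  breaks = 3, labels = c("desert", "typical", "meadow"))
      df$steppe[i] <- as.character(terc)
    }
    sample_metadata(df)
  })
}

# Per-taxon environmental optima: z-scored blend of an early-burst
# Brownian trait on the tree and an i.i.d. trait, weighted by
# trait_conservatism (Pagel-lambda style). The early-burst transform
# (evolutionary rate decaying away from the root, by exp(-eb_rate t/T))
# concentrates trait divergence on deep branches, so similar optima mark
# whole clades - deep phylogenetic niche conservatism, the regime in which
# phylogenetic null models are informative about selection. Must be called
# inside an active RNG context.
simulate_traits <- function(tree, conservatism, eb_rate = 20) {
  tr_eb <- tree
  n_tip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)       # root-to-node distance
  total <- max(depth[seq_len(n_tip)])
  parent_depth <- depth[tree$edge[, 1]]
  tr_eb$edge.length <- tree$edge.length * exp(-eb_rate * parent_depth / total)
  bm <- ape::rTraitCont(tr_eb, model = "BM", sigma = 1)
  iid <- stats::rnorm(length(bm))
  zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  tr <- sqrt(conservatism) * zs(bm) + sqrt(1 - conservatism) * zs(iid)
  names(tr) <- tree$tip.label
  tr
}

#' Simulate community tables assembled under a known process
#'
#' Each sample's counts are a multinomial draw of `reads_per_sample` reads
#' from sample-specific taxon weights. The base log-weight is a shared
#' lognormal regional-abundance term plus per-sample drift noise
#' (`drift_sd`); the scenario's process modifies these weights as described
#' in [assembly_scenario()]. Deterministic given the scenario seed.
#'
#' @param scenario an [assembly_scenario()].
#' @param tree a `phylo` whose tips cover `scenario$n_taxa` taxa.
#' @param metadata a `sample_metadata` frame defining the samples.
#' @return a [community_table()] with one row per metadata row; every row
#'   sums to `reads_per_sample`.
#' @export
simulate_communities <- function(scenario, tree, metadata) {
  stopifnot(inherits(scenario, "assembly_scenario"))
  n_taxa <- scenario$n_taxa
  if (length(tree$tip.label) < n_taxa)
    stop_validation("tree has fewer tips than scenario n_taxa")
  n_samp <- nrow(metadata)
  with_seed(scenario$seed + 2L, {
    trait_all <- simulate_traits(tree, scenario$trait_conservatism)
    # regional pool: a subset of the reference phylogeny's tips. Uniform,
    # except under homogeneous selection, where a spatially uniform harsh
    # environment filters the regional pool itself toward the tolerant
    # clade (the same trait penalty applied at the pool-assembly level);
    # local communities below apply it again to abundances.
    taxa <- if (length(tree$tip.label) > n_taxa) {
      pool_w <- if (scenario$process == "homogeneous_selection")
        exp(-scenario$strength * (trait_all - 1)^2) else NULL
      sample(tree$tip.label, n_taxa, prob = pool_w)
    } else tree$tip.label
    base <- stats::rnorm(n_taxa, 0, scenario$base_sd)  # shared log-abundance
    trait <- trait_all[taxa]
    drift <- matrix(stats::rnorm(n_taxa * n_samp, 0, scenario$drift_sd),
                    n_taxa, n_samp)
    # colonization lottery for the selection processes: under strong
    # selection the regional-abundance ranking is overridden and which
    # members of the permitted clade dominate a site is set by a
    # per-sample lottery; the mixing weight vanishes as strength -> 0 so
    # the scenario degenerates to neutrality
    lottery <- matrix(stats::rnorm(n_taxa * n_samp, 0, scenario$lottery_sd),
                      n_taxa, n_samp)
    mix <- scenario$strength / (1 + scenario$strength)
    # regional pool divergence for homogenizing dispersal: mass effects
    # homogenize samples toward their REGION's pooled weight vector, and
    # the regional vectors themselves differ (divergence that, between
    # regions, reflects their isolation); scaled by `mix` so strength -> 0
    # recovers the single shared pool of neutral drift
    regions <- unique(metadata$region)
    region_off <- matrix(stats::rnorm(n_taxa * length(regions), 0, 1),
                         n_taxa, length(regions),
                         dimnames = list(NULL, regions)) * mix
    sel <- metadata[[scenario$selective_var]]
    if (is.null(sel)) stop_validation("selective_var not found in metadata")
    env_z <- as.numeric(scale(sel))
    # per-region process assignment
    proc_of <- function(region) {
      if (scenario$process != "mixed") return(scenario$process)
      pool <- c("variable_selection", "dispersal_limitation",
                "homogenizing_dispersal")
      pool[(match(region, unique(metadata$region)) - 1) %% length(pool) + 1]
    }
    # dispersal kernel geometry: taxon home sites (site centres averaged
    # over quadrats) and sample-site distances
    sites <- do.call(rbind, lapply(split(metadata, metadata$site_id), function(d)
      data.frame(site_id = d$site_id[1], latitude = mean(d$latitude),
                 longitude = mean(d$longitude))))
    home <- sample.int(nrow(sites), n_taxa, replace = TRUE)
    geo_km <- geosphere::distm(
      cbind(metadata$longitude, metadata$latitude),
      cbind(sites$longitude[home], sites$latitude[home]),
      fun = function(p1, p2) geosphere::distHaversine(p1, p2, r = 6371008.8)) / 1000
    kernel_scale <- if (scenario$strength > 0) 500 / scenario$strength else Inf
    counts <- matrix(0L, n_samp, n_taxa,
                     dimnames = list(metadata$sample_id, taxa))
    for (s in seq_len(n_samp)) {
      p <- proc_of(metadata$region[s])
      logw <- base + drift[, s]
      if (p == "variable_selection")
        logw <- (1 - mix) * base + drift[, s] + mix * lottery[, s] -
          scenario$strength * (trait - env_z[s])^2
      else if (p == "homogeneous_selection")
        # constant selective optimum one SD above the gradient mean: a
        # spatially uniform environment favouring one conserved clade
        logw <- (1 - mix) * base + drift[, s] + mix * lottery[, s] -
          scenario$strength * (trait - 1)^2
      else if (p == "dispersal_limitation")
        logw <- logw - geo_km[s, ]^2 / (2 * kernel_scale^2)
      else if (p == "homogenizing_dispersal")
        logw <- base + region_off[, metadata$region[s]] +
          drift[, s] / (1 + scenario$strength)
      w <- exp(logw - max(logw))
      counts[s, ] <- stats::rmultinom(1, scenario$reads_per_sample, w)[, 1]
    }
    community_table(counts)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [simulate_tree()], [simulate_metadata()] and
#' [simulate_communities()] for one scenario.
#'
#' @param scenario an [assembly_scenario()].
#' @param ultrametric passed to [simulate_tree()].
#' @return list with elements `table`, `tree`, `metadata`, `scenario`.
#' @export
simulate_dataset <- function(scenario, ultrametric = FALSE) {
  tree <- simulate_tree(scenario$tree_tips %||% scenario$n_taxa,
                        seed = scenario$seed, ultrametric = ultrametric)
  metadata <- simulate_metadata(scenario)
  table <- simulate_communities(scenario, tree, metadata)
  list(table = table, tree = tree, metadata = metadata, scenario = scenario)
}

# Sample pairs where the generating process is expected to leave its
# signature (used by recovery checks): opposite ends of the selective
# gradient for variable selection, distant pairs for dispersal limitation,
# within-region pairs for homogenizing dispersal, all pairs otherwise.
targeted_pairs <- function(scenario, metadata) {
  n <- nrow(metadata)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- switch(scenario$process,
    variable_selection = {
      v <- metadata[[scenario$selective_var]]
      lo <- v <= stats::quantile(v, 1 / 3); hi <- v >= stats::quantile(v, 2 / 3)
      (lo[idx[, 1]] & hi[idx[, 2]]) | (hi[idx[, 1]] & lo[idx[, 2]])
    },
    dispersal_limitation = {
      d <- geographic_distance(metadata)
      dv <- unclass(d)[idx]
      dv >= stats::median(dv)
    },
    homogenizing_dispersal =
      metadata$region[idx[, 1]] == metadata$region[idx[, 2]],
    rep(TRUE, nrow(idx)))
  data.frame(i = metadata$sample_id[idx[keep, 1]],
             j = metadata$sample_id[idx[keep, 2]],
             stringsAsFactors = FALSE)
}
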
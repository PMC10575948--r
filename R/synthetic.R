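# Synthetic activity datasets with planted scaffold structure.
#
# Molecules are assembled by substituting small acyclic fragments (methyl,
# chloro, hydroxyl, acetyl, aldehyde, alkyl chains, ...) onto ring-scaffold
# SMILES templates (single rings, or two rings joined by short linkers), so
# every emitted SMILES is valid, has a non-empty Bemis-Murcko scaffold, and
# all members of a template group share one scaffold. Labels follow
# label = scaffold base + sum(substituent effects) (+ planted cliff) (+ noise),
# with the full ground truth recorded for oracle tests.

SUBSTITUENTS <- data.frame(
  name   = c("methyl", "ethyl", "propyl", "chloro", "fluoro", "hydroxyl",
             "amino", "acetyl", "aldehyde", "methoxy"),
  prefix = c("C", "CC", "CCC", "Cl", "F", "O", "N", "CC(=O)", "O=C", "CO"),
  branch = c("C", "CC", "CCC", "Cl", "F", "O", "N", "C(C)=O", "C=O", "OC"),
  effect = c(0.10, -0.15, -0.30, 0.35, 0.20, 0.40, 0.25, -0.20, -0.35, 0.15),
  stringsAsFactors = FALSE
)

# Core-ring patterns. The attachment atom (prefix slot) must keep the same
# ring environment in every pattern, otherwise bare/mono/di members of one
# template would carry different Murcko scaffolds.
RING1 <- list(
  benzene     = list(pure = "c1ccccc1",  p = "%sc1ccccc1",
                     m = "%sc1ccc(%s)cc1", d = "%sc1ccc(%s)c(%s)c1"),
  cyclohexane = list(pure = "C1CCCCC1",  p = "%sC1CCCCC1",
                     m = "%sC1CCC(%s)CC1", d = "%sC1CCC(%s)C(%s)C1"),
  pyridine    = list(pure = "c1ccncc1",  p = "%sc1ccncc1",
                     m = "%sc1cc(%s)ncc1", d = "%sc1cc(%s)nc(%s)c1"),
  thiophene   = list(pure = "c1ccsc1",   p = "%sc1ccsc1",
                     m = "%sc1cc(%s)sc1", d = "%sc1cc(%s)sc1%s"),
  furan       = list(pure = "c1ccoc1",   p = "%sc1ccoc1",
                     m = "%sc1cc(%s)oc1", d = "%sc1cc(%s)oc1%s"),
  pyrrole     = list(pure = "c1cc[nH]c1", p = "%sc1cc[nH]c1",
                     m = "%sc1cc(%s)[nH]c1", d = "%sc1cc(%s)[nH]c1%s"),
  oxane       = list(pure = "C1CCOCC1",  p = "%sC1CCOCC1",
                     m = "%sC1CC(%s)OCC1", d = "%sC1CC(%s)OC(%s)C1")
)

# Second-ring fragments attachable as a SMILES prefix.
RING2 <- c("c2ccccc2", "c2ccncc2", "c2cccnc2", "c2cncnc2", "c2cnccn2",
           "c2ccoc2", "c2ccsc2", "c2cc[nH]c2", "c2nccs2", "c2ncc[nH]2",
           "C2CC2", "C2CCC2", "C2CCCC2", "C2CCCCC2", "C2CCCCCC2",
           "C2CCNCC2", "C2CCOCC2", "C2CCSCC2", "c2ccc3ccccc3c2",
           "c2ccc3[nH]ccc3c2")

LINKERS <- c("", "C", "CC", "CCC", "CCCC", "O", "OC", "C(=O)")

# Deterministic scaffold template table: one row per (ring1, prefix) combo
# with sprintf patterns for 0, 1 and 2 substituents.
scaffold_templates <- function() {
  rows <- list()
  for (r1 in names(RING1)) {
    base <- RING1[[r1]]
    prefixes <- c("", as.vector(outer(RING2, LINKERS, paste0)))
    for (px in prefixes) {
      rows[[length(rows) + 1]] <- data.frame(
        pure = sprintf(base$p, px),
        mono = sprintf(base$m, px, "%s"),
        di = sprintf(base$d, px, "%s", "%s"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Library of unique scaffolds with their substitution patterns; canonical
# scaffolds computed once per session (cached by the backend layer).
scaffold_library <- function() {
  if (!is.null(.chem_cache$scaffold_library)) return(.chem_cache$scaffold_library)
  tpl <- scaffold_templates()
  can <- chem_canon(tpl$pure)
  tpl$scaffold <- can$scaffold
  tpl <- tpl[can$valid & !duplicated(tpl$scaffold), , drop = FALSE]
  rownames(tpl) <- NULL
  .chem_cache$scaffold_library <- tpl
  tpl
}

# All substituted variants of one template, in a fixed enumeration order:
# the bare scaffold, all mono-substitutions, all ordered di-substitutions.
template_variants <- function(tpl_row) {
  subs <- SUBSTITUENTS
  mono <- sprintf(tpl_row$mono, subs$branch)
  pairs <- expand.grid(i = seq_len(nrow(subs)), j = seq_len(nrow(subs)))
  di <- sprintf(tpl_row$di, subs$branch[pairs$i], subs$branch[pairs$j])
  data.frame(
    smiles = c(tpl_row$pure, mono, di),
    effect = c(0, subs$effect, subs$effect[pairs$i] + subs$effect[pairs$j]),
    substituents = c("", subs$name, paste(subs$name[pairs$i], subs$name[pairs$j],
                                          sep = "+")),
    stringsAsFactors = FALSE)
}

rskewnorm <- function(n, xi, omega, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- abs(stats::rnorm(n)); u1 <- stats::rnorm(n)
  xi + omega * (delta * u0 + sqrt(1 - delta^2) * u1)
}

#' Specify a synthetic activity dataset
#'
#' The defaults are the opioid-like study conditions: 100 scaffolds,
#' ordinary groups of 2-6 analogs, 10% activity-cliff scaffolds enlarged to
#' 18-30 analogs so they carry roughly 40% of the molecules, a right-skewed
#' scaffold-base pIC50 distribution, a 30% positive rate at cutoff 6, cliff
#' magnitude 2.5 log units, and 10% near-cutoff edge groups.
#'
#' @param n_scaffolds Number of scaffold groups.
#' @param molecules_per_scaffold Integer range (min, max) of ordinary group
#'   sizes.
#' @param ac_scaffold_fraction Fraction of scaffolds with a planted cliff.
#' @param ac_group_size Integer range of AC group sizes.
#' @param cliff_magnitude Planted cliff size in pIC50 units (>= 0).
#' @param base_xi,base_omega,base_alpha Skew-normal location, scale and
#'   shape of the scaffold-base pIC50 distribution (alpha > 0 gives the
#'   right skew seen in screening data).
#' @param substituent_effect_scale Multiplier on the per-substituent label
#'   effects (at 1, non-cliff group spans stay below 1.4 log units).
#' @param edge_group_fraction Fraction of scaffolds planted as near-cutoff
#'   edge groups (members squashed into pIC50 5.1-6.9, straddling 6).
#' @param target_positive_rate Calibrated positive rate at `cutoff` (NULL
#'   disables the calibration shift).
#' @param cutoff Activity cutoff used for the calibration (default 6).
#' @param noise Noise model: `list(type = "none")`,
#'   `list(type = "gaussian", sd = )`, or
#'   `list(type = "heteroscedastic", sd = , k = , y0 = )` where the local
#'   standard deviation is `sd + k * |y - y0|`.
#' @param seed Integer seed; the only randomness source.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_scaffolds = 100, molecules_per_scaffold = c(2, 6),
                           ac_scaffold_fraction = 0.1, ac_group_size = c(18, 30),
                           cliff_magnitude = 2.5, base_xi = 4.5,
                           base_omega = 1.2, base_alpha = 3,
                           substituent_effect_scale = 1,
                           edge_group_fraction = 0.1,
                           target_positive_rate = 0.3, cutoff = 6.0,
                           noise = list(type = "none"), seed = 0) {
  stopifnot(ac_scaffold_fraction >= 0, ac_scaffold_fraction <= 1,
            edge_group_fraction >= 0, edge_group_fraction <= 1,
            cliff_magnitude >= 0, length(molecules_per_scaffold) == 2)
  if (ac_scaffold_fraction > 0 && ac_group_size[2] < 2) {
    stop("activity cliffs need groups of at least 2 molecules")
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Preset synthetic specs
#'
#' "opioid-like" is the default [synthetic_spec()]; "balanced" targets a 50%
#' positive rate; "imbalanced" a 10% rate; "edge-enriched" plants 40% edge
#' groups with moderate Gaussian label noise for cutoff studies.
#'
#' @param preset Preset name.
#' @param seed Seed forwarded to the spec.
#' @return A `synthetic_spec`.
#' @export
synthetic_preset <- function(preset = c("opioid-like", "balanced",
                                        "imbalanced", "edge-enriched"),
                             seed = 0) {
  preset <- match.arg(preset)
  switch(preset,
    "opioid-like" = synthetic_spec(seed = seed),
    "balanced" = synthetic_spec(target_positive_rate = 0.5, seed = seed),
    "imbalanced" = synthetic_spec(target_positive_rate = 0.1, seed = seed),
    "edge-enriched" = synthetic_spec(n_scaffolds = 200,
                                     molecules_per_scaffold = c(4, 10),
                                     edge_group_fraction = 0.4,
                                     target_positive_rate = 0.4,
                                     noise = list(type = "gaussian", sd = 0.4),
                                     seed = seed))
}

#' Generate a synthetic activity dataset with ground truth
#'
#' See [synthetic_spec()] for the label model. The returned dataset is a
#' drop-in substitute for a curated activity table; the ground truth records
#' scaffold bases, planted-cliff and edge flags, and per-molecule noiseless
#' labels and effective substituent effects, so that
#' `noiseless_label == base + effect` holds exactly and planted cliffs have
#' noiseless span >= `cliff_magnitude` by construction.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `dataset` (a regression `curated_dataset`) and
#'   `ground_truth` (list of `scaffolds` and `molecules` data.frames).
#' @export
generate_activity_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lib <- scaffold_library()
  if (spec$n_scaffolds > nrow(lib)) {
    stop("n_scaffolds exceeds the enumerable scaffold library (",
         nrow(lib), ")")
  }
  n_ac <- round(spec$ac_scaffold_fraction * spec$n_scaffolds)
  n_edge <- round(spec$edge_group_fraction * spec$n_scaffolds)
  if (n_ac + n_edge > spec$n_scaffolds) stop("ac + edge fractions exceed 1")

  res <- withr::with_seed(spec$seed, {
    pick <- sample.int(nrow(lib), spec$n_scaffolds)
    roles <- rep("plain", spec$n_scaffolds)
    special <- sample.int(spec$n_scaffolds, n_ac + n_edge)
    roles[special[seq_len(n_ac)]] <- "ac"
    if (n_edge > 0) roles[special[n_ac + seq_len(n_edge)]] <- "edge"

    sizes <- integer(spec$n_scaffolds)
    mps <- spec$molecules_per_scaffold
    for (i in seq_len(spec$n_scaffolds)) {
      sizes[i] <- if (roles[i] == "ac") {
        sample(spec$ac_group_size[1]:spec$ac_group_size[2], 1)
      } else {
        max(2L, sample(mps[1]:mps[2], 1))
      }
    }

    groups <- vector("list", spec$n_scaffolds)
    for (i in seq_len(spec$n_scaffolds)) {
      variants <- template_variants(lib[pick[i], ])
      take <- sample.int(nrow(variants), min(nrow(variants), sizes[i] + 10))
      groups[[i]] <- variants[take, , drop = FALSE]
    }

    bases <- rskewnorm(spec$n_scaffolds, spec$base_xi, spec$base_omega,
                       spec$base_alpha)
    bases[roles == "edge"] <- spec$cutoff
    list(pick = pick, roles = roles, sizes = sizes, groups = groups,
         bases = bases,
         carrier = vapply(sizes, function(s) sample.int(s, 1), integer(1)))
  })

  # canonicalize all candidates in one backend batch, then dedupe per group
  all_cand <- unlist(lapply(res$groups, `[[`, "smiles"))
  can <- chem_canon(all_cand)
  stopifnot(all(can$valid))
  offset <- 0
  mol_rows <- vector("list", spec$n_scaffolds)
  for (i in seq_len(spec$n_scaffolds)) {
    g <- res$groups[[i]]
    g$canonical <- can$canonical[offset + seq_len(nrow(g))]
    offset <- offset + nrow(g)
    g <- g[!duplicated(g$canonical), , drop = FALSE]
    if (nrow(g) < res$sizes[i]) {
      stop("scaffold group ", i, " cannot reach size ", res$sizes[i])
    }
    g <- g[seq_len(res$sizes[i]), , drop = FALSE]
    g$scaffold_idx <- i
    mol_rows[[i]] <- g
  }
  mol <- do.call(rbind, mol_rows)
  scaffold_smiles <- lib$scaffold[res$pick]
  mol$scaffold <- scaffold_smiles[mol$scaffold_idx]

  # noiseless labels
  mol$label <- res$bases[mol$scaffold_idx] +
    spec$substituent_effect_scale * mol$effect
  for (i in which(res$roles == "ac")) {
    idx <- which(mol$scaffold_idx == i)
    carrier <- idx[min(res$carrier[i], length(idx))]
    others <- setdiff(idx, carrier)
    mol$label[carrier] <- max(mol$label[others]) + spec$cliff_magnitude
  }
  for (i in which(res$roles == "edge")) {
    idx <- which(mol$scaffold_idx == i)
    centered <- mol$label[idx] - mean(mol$label[idx])
    spread <- max(abs(centered))
    # squash edge-group members to within ~0.45 log units of the cutoff:
    # close enough that assay-scale noise flips their binarized class
    scaled <- if (spread > 0) 0.45 * centered / max(spread, 0.45) else centered
    l <- spec$cutoff + scaled
    if (!any(l < spec$cutoff)) l[which.min(l)] <- spec$cutoff - 0.3
    if (!any(l >= spec$cutoff)) l[which.max(l)] <- spec$cutoff + 0.3
    mol$label[idx] <- l
  }

  # calibrate the positive rate by shifting non-edge scaffold bases
  if (!is.null(spec$target_positive_rate)) {
    movable <- res$roles[mol$scaffold_idx] != "edge"
    shift <- calibrate_shift(mol$label, movable, spec$cutoff,
                             spec$target_positive_rate)
    mol$label[movable] <- mol$label[movable] + shift
    res$bases[res$roles != "edge"] <- res$bases[res$roles != "edge"] + shift
  }

  mol$id <- sprintf("S%05d", seq_len(nrow(mol)))
  noiseless <- mol$label
  gt_scaffolds <- data.frame(
    scaffold = scaffold_smiles,
    base = res$bases,
    is_ac = res$roles == "ac",
    is_edge_group = res$roles == "edge",
    size = res$sizes,
    stringsAsFactors = FALSE)
  gt_molecules <- data.frame(
    id = mol$id, scaffold = mol$scaffold,
    noiseless_label = noiseless,
    base = res$bases[mol$scaffold_idx],
    effect = noiseless - res$bases[mol$scaffold_idx],
    substituents = mol$substituents,
    is_ac = res$roles[mol$scaffold_idx] == "ac",
    is_edge = res$roles[mol$scaffold_idx] == "edge",
    stringsAsFactors = FALSE)

  data <- data.frame(id = mol$id, smiles_raw = mol$smiles,
                     smiles = mol$canonical,
                     smiles_length = nchar(mol$smiles),
                     scaffold = mol$scaffold, label = mol$label,
                     stringsAsFactors = FALSE)
  dataset <- new_curated_dataset(
    sprintf("synthetic_seed%d", spec$seed), "regression", data,
    curation_log = list(generator = "qsareval", seed = spec$seed))
  dataset$spec <- spec

  if (!identical(spec$noise$type, "none")) {
    dataset <- add_label_noise(dataset, spec$noise, seed = spec$seed + 10000L)
  }
  list(dataset = dataset,
       ground_truth = list(scaffolds = gt_scaffolds, molecules = gt_molecules))
}

# Choose the shift of movable labels that brings the positive rate at the
# cutoff closest to the target (piecewise-constant objective; scan the
# crossing points).
calibrate_shift <- function(labels, movable, cutoff, target) {
  n <- length(labels)
  fixed_pos <- sum(labels[!movable] >= cutoff)
  mv <- sort(labels[movable], decreasing = TRUE)
  # shifting by s makes movable molecules with label >= cutoff - s positive
  cand <- c(cutoff - mv - 1e-9, cutoff - mv + 1e-9, 0)
  rates <- vapply(cand, function(s) (fixed_pos + sum(mv + s >= cutoff)) / n,
                  numeric(1))
  cand[which.min(abs(rates - target))]
}

#' Add label noise to a regression dataset
#'
#' Gaussian: iid N(0, sd). Heteroscedastic: N(0, (sd + k * |y - y0|)^2),
#' mimicking potency measurements whose error grows away from the assay's
#' reference point. Clean labels are retained in `$clean_labels`.
#'
#' @param dataset A regression `curated_dataset`.
#' @param model `list(type = "gaussian", sd = )` or
#'   `list(type = "heteroscedastic", sd = , k = , y0 = )`.
#' @param seed Integer seed.
#' @return The dataset with perturbed labels.
#' @export
add_label_noise <- function(dataset, model, seed = 0) {
  stopifnot(inherits(dataset, "curated_dataset"))
  if (dataset$task != "regression") stop("noise applies to regression labels")
  type <- match.arg(model$type, c("none", "gaussian", "heteroscedastic"))
  if (type == "none") return(dataset)
  sd0 <- model$sd %||% 0
  if (sd0 < 0) stop("negative noise sd")
  y <- dataset$data$label
  sds <- if (type == "gaussian") rep(sd0, length(y)) else {
    k <- model$k %||% 0; y0 <- model$y0 %||% 6
    if (k < 0) stop("negative heteroscedastic slope")
    sd0 + k * abs(y - y0)
  }
  noise <- withr::with_seed(seed, stats::rnorm(length(y), 0, sds))
  out <- dataset
  out$clean_labels <- stats::setNames(y, dataset$data$id)
  out$data$label <- y + noise
  out$curation_log$noise <- model
  out
}

#' Generate a molecular-descriptor regression dataset
#'
#' Samples molecules from the internal template library (or a user-supplied
#' SMILES file) and labels each one with a descriptor computed from its
#' structure (MolWt or NumAtoms), so labels are exactly recomputable from
#' the SMILES. Used for the dataset-size ladder study.
#'
#' @param size Number of molecules (>= 10; errors beyond the enumerable
#'   library when sampling without replacement).
#' @param property "MolWt" or "NumAtoms".
#' @param seed Integer seed.
#' @param smiles_file Optional newline-delimited SMILES file to sample from
#'   instead of the internal library.
#' @return A regression `curated_dataset`.
#' @export
generate_descriptor_dataset <- function(size, property = c("MolWt", "NumAtoms"),
                                        seed = 0, smiles_file = NULL) {
  property <- match.arg(property)
  stopifnot(size >= 10)
  if (is.null(smiles_file)) {
    pool <- descriptor_pool()
  } else {
    smi <- readLines(smiles_file)
    can <- chem_canon(smi)
    pool <- data.frame(canonical = unique(can$canonical[can$valid]),
                       stringsAsFactors = FALSE)
    pool$scaffold <- chem_canon(pool$canonical)$scaffold
  }
  if (size > nrow(pool)) {
    stop("size ", size, " exceeds the molecule pool (", nrow(pool), ")")
  }
  take <- withr::with_seed(seed, sample.int(nrow(pool), size))
  data <- data.frame(id = sprintf("D%06d", seq_len(size)),
                     smiles_raw = pool$canonical[take],
                     smiles = pool$canonical[take],
                     smiles_length = nchar(pool$canonical[take]),
                     scaffold = pool$scaffold[take],
                     stringsAsFactors = FALSE)
  feats <- compute_representation("PhysChem", data)
  data$label <- unname(unclass(feats)[, property])
  new_curated_dataset(sprintf("%s_%d_seed%d", tolower(property), size, seed),
                      "regression", data,
                      curation_log = list(generator = "descriptor",
                                          property = property, seed = seed))
}

# Full enumeration of the template library (cached): every scaffold with
# every substitution variant, deduplicated by canonical SMILES.
descriptor_pool <- function() {
  if (!is.null(.chem_cache$descriptor_pool)) return(.chem_cache$descriptor_pool)
  lib <- scaffold_library()
  cand <- do.call(rbind, lapply(seq_len(nrow(lib)), function(i) {
    v <- template_variants(lib[i, ])
    v$scaffold <- lib$scaffold[i]
    v
  }))
  can <- chem_canon(cand$smiles)
  pool <- data.frame(canonical = can$canonical, scaffold = cand$scaffold,
                     stringsAsFactors = FALSE)
  pool <- pool[can$valid & !duplicated(pool$canonical), , drop = FALSE]
  rownames(pool) <- NULL
  .chem_cache$descriptor_pool <- pool
  pool
}

#' The dataset-size ladder
#'
#' The 16 sizes used for the descriptor-dataset study, spanning 0.1K to
#' 100K.
#'
#' @return Integer vector of dataset sizes.
#' @export
ladder_sizes <- function() {
  as.integer(1000 * c(0.1, 0.2, 0.4, 0.6, 0.8, 1, 2, 4, 6, 8, 10, 20, 40, 60,
                      80, 100))
}
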
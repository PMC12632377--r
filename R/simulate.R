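#' Default LSD-panel genotypes and disease classes
#'
#' The default simulated panel mirrors a 23-gene lysosomal storage disorder
#' knockout collection plus its parental control: six sphingolipidosis genes,
#' twelve neuronal ceroid lipofuscinosis (NCL) genes and five genes encoding
#' integral lysosomal membrane / other proteins (IMPD).
#'
#' @return named character vector mapping genotype label to disease class.
#' @export
default_disease_classes <- function() {
  c(Control = "Control",
    setNames(rep("Sphingolipidoses", 6),
             paste0(c("GBA1", "ASAH1", "HEXA", "HEXB", "PSAP", "SMPD1"), "_KO")),
    setNames(rep("NCL", 12),
             paste0(c("CLN1", "CLN2", "CLN3", "DNAJC5", "CLN5", "CLN6",
                      "CLN7", "CLN8", "ATP13A2", "GRN", "CTSD", "CTSF"), "_KO")),
    setNames(rep("IMPD", 5),
             paste0(c("MCOLN1", "NPC1", "NPC2", "LIPA", "GAA"), "_KO")))
}

#' Default organelle annotation layout
#'
#' Twenty overlapping subcellular/functional annotations typical of an
#' organelle-resolved proteomics catalog. Nested sets (e.g. OXPHOS inside
#' mitochondria) are expressed through the `parent` column; sizes are chosen
#' so the catalog covers roughly half of a 5,000-protein proteome with
#' realistic compartment proportions.
#'
#' @return data.frame with columns `label`, `size`, `parent`.
#' @export
default_annotations <- function() {
  data.frame(
    label = c("mitochondria", "OXPHOS", "mito_matrix", "mito_complexI",
              "lysosome", "endosome", "recycling_endosome", "early_endosome",
              "ER", "Golgi", "nucleus", "synapse", "SynapseSV", "SynGO",
              "vATPase", "peroxisome", "plasma_membrane", "cytoskeleton",
              "ribosome", "proteasome"),
    size = c(500L, 120L, 150L, 45L,
             300L, 250L, 120L, 150L,
             500L, 250L, 800L, 400L, 150L, 200L,
             25L, 100L, 500L, 300L,
             150L, 60L),
    parent = c(NA, "mitochondria", "mitochondria", "OXPHOS",
               NA, NA, "endosome", "endosome",
               NA, NA, NA, NA, "synapse", "synapse",
               NA, NA, NA, NA,
               NA, NA),
    stringsAsFactors = FALSE)
}

default_annotation_groups <- function(labels) {
  groups <- list(
    mitochondrial = c("mitochondria", "OXPHOS", "mito_matrix", "mito_complexI"),
    vesicular = c("lysosome", "endosome", "recycling_endosome",
                  "early_endosome", "synapse", "SynapseSV", "SynGO", "vATPase"))
  lapply(groups, function(g) intersect(g, labels))
}

#' Simulation configuration
#'
#' Defines a multi-genotype proteome simulation with planted annotation-level
#' mean log2 shifts. Replicate intensities are log-normal: protein baselines
#' are drawn in log2 space, planted shifts and i.i.d. Gaussian noise are added
#' in log2 space, and entries are masked missing completely at random.
#'
#' @param n_proteins number of simulated proteins.
#' @param genotypes genotype labels including the control (first by
#'   convention when `control_genotype` is not given).
#' @param cell_types subset of `iN`/`iDA`/`HeLa`.
#' @param n_replicates replicates per genotype-by-cell-type group (>= 2).
#' @param annotations data.frame `label`, `size`, `parent` (NA for none);
#'   nested sets are drawn from their parent's members.
#' @param effects data.frame `genotype`, `cell_type`, `annotation`, `delta`
#'   of planted mean log2 shifts (empty for the null model). Two deltas for
#'   the same (genotype, cell_type, annotation) are contradictory and
#'   rejected; a protein in several affected annotations receives the sum.
#' @param noise_sd replicate noise SD in log2 units.
#' @param baseline_mean,baseline_sd protein baseline distribution in log2
#'   units.
#' @param missing_rate completely-at-random missingness probability.
#' @param effect_sd relative per-protein heterogeneity of planted effects: a
#'   protein's shift is `delta * (1 + N(0, effect_sd))`, drawn once per
#'   annotation and shared across all conditions affected through that
#'   annotation. 0 (default) plants the same shift in every member; positive
#'   values give similarly-affected genotypes correlated fold-change
#'   profiles, as in real organelle remodelling.
#' @param disjoint when `TRUE`, top-level annotations are carved from a
#'   random permutation of the proteome without overlap (nested annotations
#'   still subset their parent). Default `FALSE`: members are sampled
#'   independently per annotation, so sets overlap by chance as real catalogs
#'   do. Disjoint layouts give controlled specificity experiments where a
#'   planted effect cannot leak into an unrelated annotation.
#' @param control_genotype control label (default `"Control"`).
#' @param seed integer seed; the same configuration always reproduces the
#'   same data bit-for-bit.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_proteins = 5000,
                       genotypes = names(default_disease_classes()),
                       cell_types = c("iN", "iDA"),
                       n_replicates = 3,
                       annotations = default_annotations(),
                       effects = NULL,
                       noise_sd = 0.25,
                       baseline_mean = 25,
                       baseline_sd = 2,
                       missing_rate = 0.05,
                       effect_sd = 0,
                       disjoint = FALSE,
                       control_genotype = "Control",
                       seed = 1) {
  if (n_replicates < 2) stopf("n_replicates must be >= 2")
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must be in [0, 1)")
  if (noise_sd < 0 || baseline_sd < 0 || effect_sd < 0) {
    stopf("noise_sd, baseline_sd and effect_sd must be >= 0")
  }
  if (!control_genotype %in% genotypes) {
    stopf("control genotype '%s' not among genotypes", control_genotype)
  }
  if (!all(cell_types %in% .cell_types)) stopf("unknown cell type")
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (any(annotations$size > n_proteins)) {
    stopf("annotation size exceeds n_proteins")
  }
  if (is.null(effects)) {
    effects <- data.frame(genotype = character(), cell_type = character(),
                          annotation = character(), delta = numeric(),
                          stringsAsFactors = FALSE)
  }
  effects <- as.data.frame(effects, stringsAsFactors = FALSE)
  if (nrow(effects) > 0) {
    key <- paste(effects$genotype, effects$cell_type, effects$annotation)
    if (anyDuplicated(key)) {
      stopf("contradictory effects: duplicate delta for %s",
            key[duplicated(key)][1])
    }
    unknown <- setdiff(effects$annotation, annotations$label)
    if (length(unknown) > 0) {
      stopf("effect references unknown annotation(s): %s",
            paste(unknown, collapse = ", "))
    }
    if (any(effects$genotype == control_genotype)) {
      stopf("planted effects on the control genotype are not allowed")
    }
  }
  structure(list(n_proteins = n_proteins, genotypes = genotypes,
                 cell_types = cell_types, n_replicates = n_replicates,
                 annotations = annotations, effects = effects,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, missing_rate = missing_rate,
                 effect_sd = effect_sd, disjoint = disjoint,
                 control_genotype = control_genotype, seed = seed),
            class = "sim_config")
}

sim_protein_ids <- function(n) sprintf("P%05d", seq_len(n))

# deterministic annotation membership: top-level sets sampled from the
# proteome, nested sets from their parent's members
sim_catalog <- function(cfg) {
  ids <- sim_protein_ids(cfg$n_proteins)
  sets <- list()
  with_seed(seed_stream(cfg$seed, "catalog"), {
    top <- is.na(cfg$annotations$parent)
    if (isTRUE(cfg$disjoint)) {
      if (sum(cfg$annotations$size[top]) > cfg$n_proteins) {
        stopf("disjoint layout needs total top-level size <= n_proteins")
      }
      pool_disjoint <- sample(ids)
      offset <- 0L
    }
    for (i in seq_len(nrow(cfg$annotations))) {
      lbl <- cfg$annotations$label[i]
      size <- cfg$annotations$size[i]
      parent <- cfg$annotations$parent[i]
      if (is.na(parent)) {
        if (isTRUE(cfg$disjoint)) {
          sets[[lbl]] <- sort(pool_disjoint[offset + seq_len(size)])
          offset <- offset + size
          next
        }
        pool <- ids
      } else {
        pool <- sets[[parent]]
        if (is.null(pool)) {
          stopf("annotation '%s' declared before its parent '%s'", lbl, parent)
        }
      }
      if (size > length(pool)) {
        stopf("annotation '%s' larger than its parent pool", lbl)
      }
      sets[[lbl]] <- sort(sample(pool, size))
    }
  })
  classes <- default_disease_classes()
  classes <- classes[names(classes) %in% cfg$genotypes]
  annotation_catalog(sets,
                     groups = default_annotation_groups(names(sets)),
                     disease_class = classes)
}

# per-protein planted shift vectors, one column per condition (all
# genotype-by-cell-type combinations, control included with zero shift)
sim_truth <- function(cfg, catalog) {
  ids <- sim_protein_ids(cfg$n_proteins)
  conds <- expand.grid(genotype = cfg$genotypes, cell_type = cfg$cell_types,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  shifts <- matrix(0, nrow = cfg$n_proteins, ncol = nrow(conds),
                   dimnames = list(ids, condition_id(conds$genotype,
                                                     conds$cell_type)))
  # per-annotation heterogeneity profile, shared across every condition the
  # annotation is planted in
  het <- list()
  with_seed(seed_stream(cfg$seed, "effect-heterogeneity"), {
    for (lbl in sort(unique(cfg$effects$annotation))) {
      members <- catalog$sets[[lbl]]
      het[[lbl]] <- setNames(1 + rnorm(length(members), 0, cfg$effect_sd),
                             members)
    }
  })
  ann_means <- cfg$effects
  if (nrow(cfg$effects) > 0) {
    ann_means$realized_mean <- NA_real_
    for (i in seq_len(nrow(cfg$effects))) {
      lbl <- cfg$effects$annotation[i]
      members <- catalog$sets[[lbl]]
      shift_i <- cfg$effects$delta[i] * het[[lbl]][members]
      col <- condition_id(cfg$effects$genotype[i], cfg$effects$cell_type[i])
      shifts[members, col] <- shifts[members, col] + shift_i
      ann_means$realized_mean[i] <- mean(shift_i)
    }
  }
  list(conditions = conds, shifts = shifts, annotation_effects = ann_means,
       membership = catalog$sets, config = cfg)
}

sim_noise_and_missing <- function(cfg, values) {
  if (cfg$noise_sd > 0) {
    noise <- with_seed(seed_stream(cfg$seed, "noise"),
                       rnorm(length(values), 0, cfg$noise_sd))
    values <- values + noise
  }
  if (cfg$missing_rate > 0) {
    mask <- with_seed(seed_stream(cfg$seed, "missing"),
                      runif(length(values)) < cfg$missing_rate)
    values[mask] <- NA_real_
  }
  values
}

#' Simulate a multi-genotype whole-cell proteome landscape
#'
#' Generates a whole-cell abundance matrix over all genotype-by-cell-type
#' groups of the configuration, with planted annotation-level log2 shifts in
#' the non-control genotypes: sample value = protein baseline + planted shift
#' + Gaussian noise (log2 space), masked missing completely at random.
#'
#' @param cfg a [sim_config].
#' @return list with `abundance` ([abundance_matrix], log2 scale), `design`
#'   ([study_design]), `catalog` ([annotation_catalog]) and `truth` (planted
#'   per-protein shifts, realized per-annotation means, membership, config).
#' @export
simulate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  catalog <- sim_catalog(cfg)
  truth <- sim_truth(cfg, catalog)
  ids <- sim_protein_ids(cfg$n_proteins)
  baseline <- with_seed(seed_stream(cfg$seed, "baseline"),
                        rnorm(cfg$n_proteins, cfg$baseline_mean,
                              cfg$baseline_sd))
  grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      genotype = cfg$genotypes, cell_type = cfg$cell_types,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- study_design(data.frame(
    sample_id = sprintf("%s_%s_r%d", grid$genotype, grid$cell_type,
                        grid$replicate),
    genotype = grid$genotype, cell_type = grid$cell_type,
    fraction = "whole_cell", replicate = grid$replicate,
    tag_status = "not_applicable", stringsAsFactors = FALSE),
    control_genotype = cfg$control_genotype)
  cond <- condition_id(grid$genotype, grid$cell_type)
  values <- baseline + truth$shifts[, cond, drop = FALSE]
  colnames(values) <- design$sample_id
  values <- sim_noise_and_missing(cfg, values)
  list(abundance = abundance_matrix(values, scale = "log2"),
       design = design, catalog = catalog, truth = truth)
}

#' Simulate a LysoIP experiment
#'
#' Three sample groups on the `lysoip` fraction -- untagged background,
#' tagged control and tagged KO (the first non-control genotype of the
#' configuration) -- each with `n_replicates`. Tagged samples gain
#' `lyso_enrichment` log2 units on lysosome-annotated proteins; the tagged KO
#' group additionally gains each `ko_organelle_shifts` delta on that
#' annotation's members.
#'
#' @param cfg a [sim_config]; its annotation layout must contain a
#'   `"lysosome"` annotation.
#' @param lyso_enrichment log2 enrichment of lysosomal proteins in tagged
#'   immunoprecipitations over the untagged background.
#' @param ko_organelle_shifts optional data.frame `annotation`, `delta` of
#'   KO-specific co-enrichment shifts.
#' @return list as in [simulate_landscape]; `truth` additionally records the
#'   enrichment design.
#' @export
simulate_lysoip <- function(cfg, lyso_enrichment,
                            ko_organelle_shifts = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!"lysosome" %in% cfg$annotations$label) {
    stopf("simulate_lysoip requires a 'lysosome' annotation")
  }
  catalog <- sim_catalog(cfg)
  if (!is.null(ko_organelle_shifts)) {
    ko_organelle_shifts <- as.data.frame(ko_organelle_shifts,
                                         stringsAsFactors = FALSE)
    unknown <- setdiff(ko_organelle_shifts$annotation, names(catalog$sets))
    if (length(unknown) > 0) {
      stopf("ko_organelle_shifts references unknown annotation(s): %s",
            paste(unknown, collapse = ", "))
    }
  }
  ko <- setdiff(cfg$genotypes, cfg$control_genotype)[1]
  if (is.na(ko)) stopf("configuration needs at least one non-control genotype")
  ct <- cfg$cell_types[1]
  ids <- sim_protein_ids(cfg$n_proteins)
  baseline <- with_seed(seed_stream(cfg$seed, "baseline"),
                        rnorm(cfg$n_proteins, cfg$baseline_mean,
                              cfg$baseline_sd))
  reps <- seq_len(cfg$n_replicates)
  design <- study_design(data.frame(
    sample_id = c(sprintf("untagged_r%d", reps),
                  sprintf("%s_IP_r%d", cfg$control_genotype, reps),
                  sprintf("%s_IP_r%d", ko, reps)),
    genotype = rep(c(cfg$control_genotype, cfg$control_genotype, ko),
                   each = cfg$n_replicates),
    cell_type = ct, fraction = "lysoip",
    replicate = rep(reps, 3),
    tag_status = rep(c("untagged", "tagged", "tagged"),
                     each = cfg$n_replicates),
    stringsAsFactors = FALSE), control_genotype = cfg$control_genotype)
  lyso <- catalog$sets[["lysosome"]]
  tagged_shift <- setNames(numeric(cfg$n_proteins), ids)
  tagged_shift[lyso] <- lyso_enrichment
  ko_shift <- setNames(numeric(cfg$n_proteins), ids)
  if (!is.null(ko_organelle_shifts) && nrow(ko_organelle_shifts) > 0) {
    for (i in seq_len(nrow(ko_organelle_shifts))) {
      members <- catalog$sets[[ko_organelle_shifts$annotation[i]]]
      ko_shift[members] <- ko_shift[members] + ko_organelle_shifts$delta[i]
    }
  }
  group_shift <- cbind(untagged = 0 * tagged_shift,
                       tagged_control = tagged_shift,
                       tagged_ko = tagged_shift + ko_shift)
  group_of <- rep(c("untagged", "tagged_control", "tagged_ko"),
                  each = cfg$n_replicates)
  values <- baseline + group_shift[, group_of, drop = FALSE]
  dimnames(values) <- list(ids, design$sample_id)
  values <- sim_noise_and_missing(cfg, values)
  truth <- list(ko_genotype = ko, lyso_enrichment = lyso_enrichment,
                ko_organelle_shifts = ko_organelle_shifts,
                group_shift = group_shift, membership = catalog$sets,
                config = cfg)
  list(abundance = abundance_matrix(values, scale = "log2"),
       design = design, catalog = catalog, truth = truth)
}

#' Simulate a whole-cell / soma / projection spatial proteome
#'
#' Two genotypes (control plus the first non-control genotype of the
#' configuration) across three fractions with `n_replicates` each. A
#' compartment profile adds genotype-shared soma/projection deltas to an
#' annotation's members; `ko_projection_shifts` adds KO-specific deltas to
#' projection samples only, the signal the ratio-of-ratios metric isolates.
#'
#' @param cfg a [sim_config].
#' @param compartment_profiles optional data.frame `annotation`,
#'   `soma_delta`, `projection_delta` (applied identically in both
#'   genotypes).
#' @param ko_projection_shifts optional data.frame `annotation`, `delta`
#'   applied to KO projection samples.
#' @return list as in [simulate_landscape].
#' @export
simulate_spatial <- function(cfg, compartment_profiles = NULL,
                             ko_projection_shifts = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  catalog <- sim_catalog(cfg)
  check_known <- function(df, what) {
    if (is.null(df)) return(NULL)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    unknown <- setdiff(df$annotation, names(catalog$sets))
    if (length(unknown) > 0) {
      stopf("%s references unknown annotation(s): %s", what,
            paste(unknown, collapse = ", "))
    }
    df
  }
  compartment_profiles <- check_known(compartment_profiles,
                                      "compartment_profiles")
  ko_projection_shifts <- check_known(ko_projection_shifts,
                                      "ko_projection_shifts")
  ko <- setdiff(cfg$genotypes, cfg$control_genotype)[1]
  if (is.na(ko)) stopf("configuration needs at least one non-control genotype")
  ct <- cfg$cell_types[1]
  ids <- sim_protein_ids(cfg$n_proteins)
  baseline <- with_seed(seed_stream(cfg$seed, "baseline"),
                        rnorm(cfg$n_proteins, cfg$baseline_mean,
                              cfg$baseline_sd))
  fractions <- c("whole_cell", "soma", "projection")
  grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      fraction = fractions,
                      genotype = c(cfg$control_genotype, ko),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- study_design(data.frame(
    sample_id = sprintf("%s_%s_r%d", grid$genotype, grid$fraction,
                        grid$replicate),
    genotype = grid$genotype, cell_type = ct, fraction = grid$fraction,
    replicate = grid$replicate, tag_status = "not_applicable",
    stringsAsFactors = FALSE), control_genotype = cfg$control_genotype)
  frac_shift <- matrix(0, nrow = cfg$n_proteins, ncol = length(fractions),
                       dimnames = list(ids, fractions))
  if (!is.null(compartment_profiles) && nrow(compartment_profiles) > 0) {
    for (i in seq_len(nrow(compartment_profiles))) {
      members <- catalog$sets[[compartment_profiles$annotation[i]]]
      frac_shift[members, "soma"] <- frac_shift[members, "soma"] +
        compartment_profiles$soma_delta[i]
      frac_shift[members, "projection"] <- frac_shift[members, "projection"] +
        compartment_profiles$projection_delta[i]
    }
  }
  ko_proj <- setNames(numeric(cfg$n_proteins), ids)
  if (!is.null(ko_projection_shifts) && nrow(ko_projection_shifts) > 0) {
    for (i in seq_len(nrow(ko_projection_shifts))) {
      members <- catalog$sets[[ko_projection_shifts$annotation[i]]]
      ko_proj[members] <- ko_proj[members] + ko_projection_shifts$delta[i]
    }
  }
  values <- frac_shift[, grid$fraction, drop = FALSE] + baseline
  is_ko_proj <- grid$genotype == ko & grid$fraction == "projection"
  if (any(is_ko_proj)) {
    values[, is_ko_proj] <- values[, is_ko_proj] + ko_proj
  }
  dimnames(values) <- list(ids, design$sample_id)
  values <- sim_noise_and_missing(cfg, values)
  truth <- list(ko_genotype = ko, frac_shift = frac_shift,
                ko_projection_shift = ko_proj,
                compartment_profiles = compartment_profiles,
                ko_projection_shifts = ko_projection_shifts,
                membership = catalog$sets, config = cfg)
  list(abundance = abundance_matrix(values, scale = "log2"),
       design = design, catalog = catalog, truth = truth)
}
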
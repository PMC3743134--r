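# Simulation plan: parameterizes every synthetic input the pipeline consumes.

#' Gene group labels used throughout the pipeline
#'
#' The six occupancy/expression groups plus the unbound background class.
#' Pre-MBT groups describe genes occupied by Pol II before the midblastula
#' transition (MBT); MBT groups describe genes first occupied during the MBT,
#' split by maternal transcript deposition and zygotic expression level.
#'
#' @return Character vector of the seven group labels.
#' @export
gene_groups <- function() {
  c("pre-MBT not-paused", "pre-MBT dual", "pre-MBT paused",
    "MBT maternal", "MBT active", "MBT poised", "unbound")
}

pre_mbt_groups <- function() gene_groups()[1:3]
mbt_groups <- function() gene_groups()[4:6]
bound_groups <- function() gene_groups()[1:6]

#' Default per-group signal mixture weights for the read simulator
#'
#' IP reads for a bound gene are drawn from a mixture of a TSS-proximal
#' (pause-site) component and a gene-body-uniform component; `w_tss` is the
#' TSS-component weight per group and stage. Paused groups are pure
#' TSS-component (their gene bodies carry background only, so the TU
#' enrichment falls below 1); non-paused groups carry substantial body
#' signal; the dual group switches from a non-paused mixture before the MBT
#' to a paused one during it.
#'
#' @return A data frame with columns `group`, `stage`, `w_tss`.
#' @export
default_mixture_weights <- function() {
  rbind(
    data.frame(group = "pre-MBT not-paused", stage = "pre-MBT", w_tss = 0.35),
    data.frame(group = "pre-MBT dual",       stage = "pre-MBT", w_tss = 0.50),
    data.frame(group = "pre-MBT paused",     stage = "pre-MBT", w_tss = 1.00),
    data.frame(group = "pre-MBT not-paused", stage = "MBT",     w_tss = 0.35),
    data.frame(group = "pre-MBT dual",       stage = "MBT",     w_tss = 0.85),
    data.frame(group = "pre-MBT paused",     stage = "MBT",     w_tss = 1.00),
    data.frame(group = "MBT maternal",       stage = "MBT",     w_tss = 0.60),
    data.frame(group = "MBT active",         stage = "MBT",     w_tss = 0.75),
    data.frame(group = "MBT poised",         stage = "MBT",     w_tss = 0.90)
  )
}

#' Default motif planting rates per gene group
#'
#' Probability that a promoter of a gene in a given group receives a planted
#' instance of each core-promoter element, mirroring the differential usage of
#' dispersed-initiation elements (DRE, Ohler1/6/7) at maternal housekeeping
#' promoters, pausing-associated elements (Inr, DPE, PB, MTE, GAGA) at
#' MBT-zygotic promoters, and TATA/Zelda at early (pre-MBT) promoters.
#' Zelda is planted in multiple copies (see [generate_promoters()]).
#'
#' @return Numeric matrix, groups x motifs.
#' @export
default_plant_rates <- function() {
  motifs <- c("DRE", "Ohler1", "Ohler6", "Ohler7", "TATA", "Inr",
              "DPE", "PB", "MTE", "GAGA", "Zelda")
  m <- matrix(0.02, nrow = 7, ncol = length(motifs),
              dimnames = list(gene_groups(), motifs))
  m["pre-MBT not-paused", c("TATA", "Inr", "Zelda")] <- c(0.55, 0.50, 0.90)
  m["pre-MBT dual", c("TATA", "Inr", "GAGA", "PB", "Zelda")] <-
    c(0.50, 0.55, 0.45, 0.35, 0.90)
  m["pre-MBT paused", c("Inr", "GAGA", "PB", "Zelda")] <- c(0.55, 0.50, 0.40, 0.85)
  m["MBT maternal", c("DRE", "Ohler1", "Ohler6", "Ohler7")] <-
    c(0.40, 0.20, 0.20, 0.40)
  m["MBT active", c("Inr", "DPE", "PB", "MTE", "GAGA", "Zelda")] <-
    c(0.50, 0.30, 0.35, 0.10, 0.40, 0.35)
  m["MBT poised", c("Inr", "DPE", "PB", "MTE", "GAGA")] <-
    c(0.50, 0.30, 0.35, 0.10, 0.40)
  m
}

#' Build a simulation plan
#'
#' A `simulation_plan` collects every parameter of the synthetic study:
#' gene counts and group proportions, sequencing depths, fragment geometry,
#' chromosome layout, gene-structure parameters, per-group signal targets,
#' motif planting rates and PCR duplicate-stack artifacts. All generators are
#' pure functions of `(plan, seed)`.
#'
#' Group proportions default to a desk-scale version of the study structure:
#' pre-MBT genes are rare (~1% of genes), roughly a third of genes are
#' maternal, a quarter MBT-zygotic, and the rest unbound.
#'
#' @param n_genes Number of genes to simulate.
#' @param group_proportions Named fractions over [gene_groups()]; must sum
#'   to 1.
#' @param read_depth_ip,read_depth_wce Reads per IP / WCE sample.
#' @param fragment_length Library fragment (insert) size in bp; single-end
#'   reads are extended to this size downstream.
#' @param read_length Sequenced read length in bp.
#' @param chrom_sizes Named integer vector of chromosome sizes, or `NULL` to
#'   size `n_chroms` chromosomes automatically so all genes fit with ~60%
#'   headroom.
#' @param n_chroms Number of chromosomes when auto-sizing.
#' @param pre_mbt_median_width,mbt_median_width Median transcript width (bp)
#'   for pre-MBT and for all other gene groups.
#' @param width_sdlog Log-scale SD of the log-normal width distribution.
#' @param multi_tss_fraction Fraction of genes given 2-4 alternative TSSs.
#' @param shortest_tss_fraction Named fractions (`pre_mbt`, `other`) of
#'   multi-TSS genes whose active (signal-bearing) TSS yields the shortest
#'   transcript.
#' @param intronless_prob Named per-group-class probabilities (`pre_mbt`,
#'   `maternal`, `other`) that a gene is intronless.
#' @param coding_prob Named probabilities that a gene is protein-coding.
#' @param mixture_weights Data frame as [default_mixture_weights()].
#' @param occupancy_sdlog Log-normal spread of per-gene Pol II occupancy
#'   (the per-gene share of bound-gene IP reads).
#' @param motif_plant_rates Matrix as [default_plant_rates()].
#' @param stack_artifact_count Number of planted PCR duplicate stacks per IP
#'   read set.
#' @param stack_artifact_size Reads per planted stack (must exceed the
#'   default duplicate filter cutoff of 10 to be removable).
#' @param background_ip_fraction Fraction of IP depth assigned to uniform
#'   nonspecific background; the rest is split across bound genes.
#' @param rpkm_noise_sdlog Log-normal multiplicative noise SD applied to RPKM
#'   group targets.
#' @param tss_component_mean,tss_component_sd Pause-site signal component:
#'   fragment centers are drawn from a discretized normal at this TSS-relative
#'   position (bp) in transcript orientation.
#' @param seed Integer master seed.
#'
#' @return An object of class `simulation_plan`.
#' @export
simulation_plan <- function(n_genes = 1000,
                            group_proportions = c(
                              "pre-MBT not-paused" = 0.005,
                              "pre-MBT dual"       = 0.003,
                              "pre-MBT paused"     = 0.002,
                              "MBT maternal"       = 0.30,
                              "MBT active"         = 0.10,
                              "MBT poised"         = 0.15,
                              "unbound"            = 0.44),
                            read_depth_ip = 2e6,
                            read_depth_wce = 2e6,
                            fragment_length = 200,
                            read_length = 36,
                            chrom_sizes = NULL,
                            n_chroms = 2,
                            pre_mbt_median_width = 1200,
                            mbt_median_width = 6000,
                            width_sdlog = 0.4,
                            multi_tss_fraction = 0.33,
                            shortest_tss_fraction = c(pre_mbt = 0.63, other = 0.31),
                            intronless_prob = c(pre_mbt = 0.55, maternal = 0.07,
                                                other = 0.09),
                            coding_prob = c(pre_mbt = 0.83, other = 0.95),
                            mixture_weights = default_mixture_weights(),
                            occupancy_sdlog = 0.2,
                            motif_plant_rates = default_plant_rates(),
                            stack_artifact_count = 5,
                            stack_artifact_size = 15,
                            background_ip_fraction = 0.10,
                            rpkm_noise_sdlog = 0.25,
                            tss_component_mean = 40,
                            tss_component_sd = 50,
                            seed = 1L) {
  plan <- list(
    n_genes = as.integer(n_genes),
    group_proportions = group_proportions,
    read_depth_ip = read_depth_ip,
    read_depth_wce = read_depth_wce,
    fragment_length = as.integer(fragment_length),
    read_length = as.integer(read_length),
    chrom_sizes = chrom_sizes,
    n_chroms = as.integer(n_chroms),
    pre_mbt_median_width = pre_mbt_median_width,
    mbt_median_width = mbt_median_width,
    width_sdlog = width_sdlog,
    multi_tss_fraction = multi_tss_fraction,
    shortest_tss_fraction = shortest_tss_fraction,
    intronless_prob = intronless_prob,
    coding_prob = coding_prob,
    mixture_weights = mixture_weights,
    occupancy_sdlog = occupancy_sdlog,
    motif_plant_rates = motif_plant_rates,
    stack_artifact_count = as.integer(stack_artifact_count),
    stack_artifact_size = as.integer(stack_artifact_size),
    background_ip_fraction = background_ip_fraction,
    rpkm_noise_sdlog = rpkm_noise_sdlog,
    tss_component_mean = tss_component_mean,
    tss_component_sd = tss_component_sd,
    seed = as.integer(seed)
  )
  class(plan) <- "simulation_plan"
  validate_plan(plan)
  plan
}

validate_plan <- function(plan) {
  stopifnot(inherits(plan, "simulation_plan"))
  if (plan$n_genes < 0) stop("n_genes must be >= 0")
  gp <- plan$group_proportions
  if (!setequal(names(gp), gene_groups()))
    stop("group_proportions must be named by gene_groups()")
  if (abs(sum(gp) - 1) > 1e-9) stop("group_proportions must sum to 1")
  if (any(gp < 0)) stop("group_proportions must be non-negative")
  if (plan$read_depth_ip < 0 || plan$read_depth_wce < 0)
    stop("read depths must be >= 0")
  if (plan$fragment_length <= 0) stop("fragment_length must be > 0")
  if (plan$read_length <= 0) stop("read_length must be > 0")
  if (!is.null(plan$chrom_sizes)) {
    if (is.null(names(plan$chrom_sizes)) || any(names(plan$chrom_sizes) == ""))
      stop("chrom_sizes must be named")
    if (any(plan$chrom_sizes <= 0)) stop("chromosome sizes must be positive")
  }
  if (plan$stack_artifact_count < 0) stop("stack_artifact_count must be >= 0")
  invisible(plan)
}

#' @export
print.simulation_plan <- function(x, ...) {
  cat("simulation_plan:", x$n_genes, "genes, IP depth",
      format(x$read_depth_ip, big.mark = ","), ", WCE depth",
      format(x$read_depth_wce, big.mark = ","), ", fragment",
      x$fragment_length, "bp, seed", x$seed, "\n")
  props <- paste0(names(x$group_proportions), "=", x$group_proportions)
  cat("  groups:", paste(props, collapse = ", "), "\n")
  invisible(x)
}

# Deterministic sub-seed for a named random stream. Folds the label into the
# master seed with a small polynomial hash, kept within 32-bit integer range.
derive_seed <- function(seed, ...) {
  label <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147480009
  as.integer((as.numeric(seed) * 48271 + h) %% 2147480009)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Largest-remainder apportionment of n items to proportions (deterministic).
apportion <- function(n, proportions) {
  raw <- proportions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    frac_order <- order(raw - base, decreasing = TRUE)
    base[frac_order[seq_len(left)]] <- base[frac_order[seq_len(left)]] + 1
  }
  as.integer(base)
}
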
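# Synthetic ChIP-seq reads and companion inputs (expression, promoters,
# conservation, expression patterns, reference ranking, TBP peaks).

sim_stages <- function() c("pre-MBT", "MBT", "post-MBT")

# Per-gene, per-component expected IP read counts. The non-background depth
# is split across bound genes (log-normal occupancy spread around an equal
# share); each gene's reads are divided between the TSS-proximal pause-site
# component and the gene-body-uniform component by the group's mixture
# weight for the stage.
.sim_gene_lambdas <- function(plan, truth, stage) {
  genes <- truth$genes
  target_stage <- if (stage == "pre-MBT") "pre-MBT" else "MBT"
  mw <- plan$mixture_weights
  mw <- mw[mw$stage == target_stage, , drop = FALSE]
  bound <- if (stage == "pre-MBT") pre_mbt_groups() else bound_groups()
  idx <- which(genes$group %in% intersect(bound, mw$group))
  if (!length(idx))
    return(data.frame(gene = integer(), lambda_tss = numeric(),
                      lambda_body = numeric()))
  w_tss <- mw$w_tss[match(genes$group[idx], mw$group)]
  occupancy <- exp(rnorm(length(idx), 0, plan$occupancy_sdlog))
  share <- occupancy / sum(occupancy)
  n_signal <- plan$read_depth_ip * (1 - plan$background_ip_fraction)
  lambda <- n_signal * share
  data.frame(gene = idx, lambda_tss = lambda * w_tss,
             lambda_body = lambda * (1 - w_tss))
}

# n uniform reads over the genome (used for WCE and IP background).
.sim_uniform_reads <- function(n, chrom_sizes, read_length) {
  if (n == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  sizes <- as.numeric(chrom_sizes)
  ch <- sample(names(chrom_sizes), n, replace = TRUE, prob = sizes)
  start <- as.integer(floor(runif(n) * (sizes[match(ch, names(chrom_sizes))] -
                                          read_length)))
  data.frame(chrom = ch, start = start, end = start + as.integer(read_length),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Reads from fragment centers: each fragment yields one sequenced end.
.reads_from_centers <- function(chrom, centers, fragment_length, read_length,
                                chrom_sizes) {
  n <- length(centers)
  if (n == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  half <- fragment_length %/% 2
  start <- ifelse(strand == "+", centers - half, centers + half - read_length)
  df <- data.frame(chrom = chrom, start = as.integer(start),
                   end = as.integer(start + read_length), strand = strand,
                   stringsAsFactors = FALSE)
  lim <- unname(chrom_sizes[df$chrom])
  df[df$start >= 0 & df$end <= lim, , drop = FALSE]
}

#' Simulate IP and WCE aligned-read sets for one stage and replicate
#'
#' WCE reads are uniform over the genome. IP reads for bound genes are drawn
#' from a mixture of a TSS-proximal component (discretized normal at +40 bp,
#' sd 50 bp, in transcript orientation: the pause-site signal) and a
#' gene-body-uniform component, with mixture weights set by the gene's true
#' label and the stage; pre-MBT stages bind only pre-MBT genes. The
#' remaining depth is uniform background. Planted PCR duplicate stacks from
#' the ground truth are appended verbatim. Deterministic per
#' (plan seed, stage, replicate).
#'
#' @param plan A [simulation_plan()].
#' @param truth Ground truth from [generate_annotation()].
#' @param stage One of `"pre-MBT"`, `"MBT"`, `"post-MBT"`.
#' @param replicate Replicate index (>= 1).
#' @return List with `ip` and `wce` [read_set()]s (unextended).
#' @export
simulate_reads <- function(plan, truth, stage, replicate = 1L) {
  validate_plan(plan)
  if (!stage %in% sim_stages())
    stop("unknown stage label: ", stage, " (expected one of ",
         paste(sim_stages(), collapse = ", "), ")")
  chrom_sizes <- truth$chrom_sizes
  rl <- plan$read_length
  fl <- plan$fragment_length

  with_seed(derive_seed(plan$seed, "reads", stage, replicate), {
    wce <- .sim_uniform_reads(plan$read_depth_wce, chrom_sizes, rl)

    ip_parts <- list()
    if (plan$read_depth_ip > 0 && nrow(truth$genes) > 0) {
      lam <- .sim_gene_lambdas(plan, truth, stage)
      if (nrow(lam)) {
        genes <- truth$genes[lam$gene, , drop = FALSE]
        n_tss <- stats::rpois(nrow(lam), lam$lambda_tss)
        n_body <- stats::rpois(nrow(lam), lam$lambda_body)
        dir <- ifelse(genes$strand == "+", 1L, -1L)
        # TSS-proximal component: pause-site fragment centers
        centers_tss <- rep(genes$tss, n_tss) + rep(dir, n_tss) *
          as.integer(round(rnorm(sum(n_tss), plan$tss_component_mean,
                                 plan$tss_component_sd)))
        # body component: uniform over the primary transcript
        body_start <- ifelse(genes$strand == "+", genes$tss,
                             genes$tss - genes$width + 1L)
        off <- floor(runif(sum(n_body)) * rep(genes$width, n_body))
        centers_body <- rep(body_start, n_body) + as.integer(off)
        ip_parts$signal <- .reads_from_centers(
          c(rep(genes$chrom, n_tss), rep(genes$chrom, n_body)),
          c(centers_tss, centers_body), fl, rl, chrom_sizes)
      }
      n_signal <- if (is.null(ip_parts$signal)) 0L else nrow(ip_parts$signal)
      n_bg <- max(0L, as.integer(plan$read_depth_ip) - n_signal)
      ip_parts$background <- .sim_uniform_reads(n_bg, chrom_sizes, rl)
    } else if (plan$read_depth_ip > 0) {
      ip_parts$background <- .sim_uniform_reads(as.integer(plan$read_depth_ip),
                                                chrom_sizes, rl)
    }
    if (plan$read_depth_ip > 0 && !is.null(truth$artifacts) &&
        nrow(truth$artifacts) > 0) {
      a <- truth$artifacts
      ip_parts$artifacts <- data.frame(
        chrom = rep(a$chrom, a$size), start = rep(a$start, a$size),
        end = rep(a$start + rl, a$size), strand = rep(a$strand, a$size),
        stringsAsFactors = FALSE)
    }
    ip <- if (length(ip_parts)) do.call(rbind, unname(ip_parts)) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), stringsAsFactors = FALSE)
    rownames(ip) <- NULL
    list(ip = read_set(ip, fl), wce = read_set(wce, fl))
  })
}

#' Generate a stage-wise expression (RPKM) table
#'
#' Group RPKM targets follow the maternal/zygotic structure the
#' classification thresholds assume: maternal genes have nc10 RPKM >= 1,
#' MBT-active genes reach nc14D RPKM >= 5 with nc10 < 1, MBT-poised genes
#' stay below 5 at nc14D. Multiplicative log-normal noise is applied, then
#' the defining bounds are enforced so planted labels remain consistent.
#' Separate maternal/zygotic nc10 components support the maternal
#' time-course filter.
#'
#' @param plan A [simulation_plan()].
#' @param truth Ground truth from [generate_annotation()].
#' @return Data frame: gene_id, nc10..nc14D, nc10_maternal, nc10_zygotic.
#' @export
generate_expression <- function(plan, truth) {
  genes <- truth$genes
  stages <- c("nc10", "nc11", "nc12", "nc13", "nc14A", "nc14B", "nc14C",
              "nc14D")
  targets <- rbind(
    "pre-MBT not-paused" = c(3, 5, 8, 10, 9, 7, 5, 4),
    "pre-MBT dual"       = c(3, 5, 8, 10, 9, 7, 5, 4),
    "pre-MBT paused"     = c(0.2, 0.4, 0.8, 2, 3, 4, 5, 6),
    "MBT maternal"       = c(10, 9, 8, 8, 8, 8, 8, 8),
    "MBT active"         = c(0.1, 0.2, 0.5, 2, 8, 15, 22, 30),
    "MBT poised"         = c(0.05, 0.05, 0.1, 0.2, 0.3, 0.5, 0.6, 0.8),
    "unbound"            = rep(0.02, 8))
  colnames(targets) <- stages
  with_seed(derive_seed(plan$seed, "expression"), {
    n <- nrow(genes)
    if (n == 0)
      return(data.frame(gene_id = character()))
    vals <- targets[genes$group, , drop = FALSE] *
      exp(matrix(rnorm(n * length(stages), 0, plan$rpkm_noise_sdlog),
                 nrow = n))
    maternal <- genes$group == "MBT maternal"
    active <- genes$group == "MBT active"
    poised <- genes$group == "MBT poised"
    vals[maternal, "nc10"] <- pmax(vals[maternal, "nc10"], 1)
    vals[active, "nc10"] <- pmin(vals[active, "nc10"], 0.99)
    vals[active, "nc14D"] <- pmax(vals[active, "nc14D"], 5)
    vals[poised, "nc14D"] <- pmin(vals[poised, "nc14D"], 4.99)
    nc10_maternal <- ifelse(maternal, vals[, "nc10"] * 0.9, 0.05) *
      exp(rnorm(n, 0, plan$rpkm_noise_sdlog))
    nc10_zygotic <- ifelse(maternal, 0.1, vals[, "nc10"]) *
      exp(rnorm(n, 0, plan$rpkm_noise_sdlog))
    out <- data.frame(gene_id = genes$gene_id, round(vals, 4),
                      nc10_maternal = round(nc10_maternal, 4),
                      nc10_zygotic = round(nc10_zygotic, 4),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

# Draw one concrete realization of an IUPAC consensus.
.realize_iupac <- function(consensus) {
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP[
    strsplit(consensus, "")[[1]]], "")
  paste(vapply(sets, function(s) s[sample.int(length(s), 1)], ""),
        collapse = "")
}

#' Generate promoter sequences with planted core-promoter elements
#'
#' One sequence per transcript spanning `-upstream..+downstream-1` around the
#' TSS in transcript orientation, with random background at ~40% GC. Motifs
#' are planted per transcript at the plan's per-group rates: a concrete
#' realization of the IUPAC consensus placed uniformly within the motif's
#' TSS-relative window (directional motifs on the sense strand;
#' non-directional motifs on a random strand). Zelda, which the analysis
#' counts per promoter rather than scoring presence only, is planted in
#' 1 + Poisson(1) copies.
#'
#' @param plan A [simulation_plan()].
#' @param truth Ground truth from [generate_annotation()].
#' @param annotation Transcript annotation from [generate_annotation()].
#' @param catalog Motif catalog; defaults to [motif_catalog()]. Plant-rate
#'   columns absent from the catalog are an error.
#' @param upstream,downstream Extent of the promoter sequence around the TSS.
#' @return List: `sequences` ([Biostrings::DNAStringSet] named by transcript
#'   id), `offset` (TSS-relative offset of the first base), `plants`
#'   (data frame of planted instances: transcript_id, motif, offset, strand).
#' @export
generate_promoters <- function(plan, truth, annotation,
                               catalog = motif_catalog(),
                               upstream = 2000, downstream = 100) {
  missing_motifs <- setdiff(colnames(plan$motif_plant_rates), catalog$name)
  if (length(missing_motifs))
    stop("motif(s) absent from catalog: ",
         paste(missing_motifs, collapse = ", "))
  len <- upstream + downstream
  with_seed(derive_seed(plan$seed, "promoters"), {
    n <- nrow(annotation)
    seqs <- character(n)
    plants <- list()
    group <- truth$genes$group[match(annotation$gene_id, truth$genes$gene_id)]
    for (i in seq_len(n)) {
      s <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.3))
      occupied <- rep(FALSE, len)
      rates <- plan$motif_plant_rates[group[i], ]
      for (mo in colnames(plan$motif_plant_rates)) {
        if (runif(1) >= rates[[mo]]) next
        def <- catalog[catalog$name == mo, ]
        copies <- if (mo == "Zelda") 1L + stats::rpois(1, 1) else 1L
        w <- nchar(def$consensus)
        for (cp in seq_len(copies)) {
          minus <- !def$directional && runif(1) < 0.5
          inst <- .realize_iupac(def$consensus)
          if (minus)
            inst <- as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(inst)))
          # candidate offsets for the 5'-most matched base (scanned
          # orientation); convert to the sense-strand start of the insert
          anchors <- seq(max(def$window_start, -upstream + (if (minus) w - 1 else 0)),
                         min(def$window_end, downstream - (if (minus) 1 else w)))
          if (!length(anchors)) next
          placed <- FALSE
          for (try in seq_len(25)) {
            o <- anchors[sample.int(length(anchors), 1)]
            j <- if (minus) o - w + 1 + upstream + 1 else o + upstream + 1
            span <- j:(j + w - 1)
            if (!any(occupied[span])) {
              s[span] <- strsplit(inst, "")[[1]]
              occupied[span] <- TRUE
              plants[[length(plants) + 1]] <- data.frame(
                transcript_id = annotation$transcript_id[i], motif = mo,
                offset = o, strand = if (minus) "-" else "+",
                stringsAsFactors = FALSE)
              placed <- TRUE
              break
            }
          }
          if (!placed) next
        }
      }
      seqs[i] <- paste(s, collapse = "")
    }
    sequences <- Biostrings::DNAStringSet(seqs)
    names(sequences) <- annotation$transcript_id
    plants <- if (length(plants)) do.call(rbind, plants) else
      data.frame(transcript_id = character(), motif = character(),
                 offset = integer(), strand = character(),
                 stringsAsFactors = FALSE)
    list(sequences = sequences, offset = -upstream, plants = plants)
  })
}

#' Generate a per-base conservation score track
#'
#' Smooth noise in [0, 1] (block-correlated at 100 bp), elevated over pre-MBT
#' gene spans to emulate their higher cross-species conservation.
#'
#' @param plan A [simulation_plan()].
#' @param truth Ground truth from [generate_annotation()].
#' @return A `score_track`: list with `coverage` (per-chrom
#'   [S4Vectors::Rle]) and `chrom_sizes`.
#' @export
generate_score_track <- function(plan, truth) {
  with_seed(derive_seed(plan$seed, "conservation"), {
    vals <- lapply(names(truth$chrom_sizes), function(ch) {
      L <- truth$chrom_sizes[[ch]]
      nb <- ceiling(L / 100)
      v <- rep(pmin(1, pmax(0, rnorm(nb, 0.25, 0.08))), each = 100)[1:L]
      pre <- truth$genes[truth$genes$group %in% pre_mbt_groups() &
                           truth$genes$chrom == ch, , drop = FALSE]
      if (nrow(pre) > 0)
        for (i in seq_len(nrow(pre))) {
          span <- (pre$start[i] + 1):min(pre$end[i], L)
          v[span] <- pmin(1, v[span] + 0.45)
        }
      S4Vectors::Rle(round(v, 3))
    })
    names(vals) <- names(truth$chrom_sizes)
    structure(list(coverage = vals, chrom_sizes = truth$chrom_sizes),
              class = "score_track")
  })
}

#' Generate a gene -> (stage, term) expression-pattern annotation table
#'
#' Emulates a large-scale in situ hybridization annotation: maternal genes
#' carry a 'maternal' first entry, MBT-active genes are first detected around
#' cellularization (stages 4-6), MBT-poised genes at post-gastrulation stages
#' (9-10); all genes may carry additional later annotations and occasional
#' 'no staining' entries.
#'
#' @param plan A [simulation_plan()].
#' @param truth Ground truth from [generate_annotation()].
#' @return Data frame: gene_id, stage (integer), term.
#' @export
generate_pattern_annotations <- function(plan, truth) {
  genes <- truth$genes
  terms_late <- c("gastrula", "germ band", "dorsal ectoderm", "mesoderm",
                  "nervous system")
  with_seed(derive_seed(plan$seed, "patterns"), {
    rows <- lapply(seq_len(nrow(genes)), function(i) {
      g <- genes$gene_id[i]
      grp <- genes$group[i]
      out <- list()
      if (grp == "MBT maternal")
        out[[length(out) + 1]] <- data.frame(gene_id = g, stage = 1L,
                                             term = "maternal")
      if (runif(1) < 0.1)
        out[[length(out) + 1]] <- data.frame(gene_id = g, stage = 2L,
                                             term = "no staining")
      first <- if (grp %in% c("MBT active", "pre-MBT not-paused",
                              "pre-MBT dual") && runif(1) < 0.8) {
        data.frame(gene_id = g, stage = sample(4:6, 1),
                   term = "cellular blastoderm")
      } else if (grp == "MBT poised" && runif(1) < 0.8) {
        data.frame(gene_id = g, stage = sample(9:10, 1), term = "germ band")
      } else {
        data.frame(gene_id = g, stage = sample(4:16, 1),
                   term = sample(c("cellular blastoderm", terms_late), 1))
      }
      out[[length(out) + 1]] <- first
      if (runif(1) < 0.5)
        out[[length(out) + 1]] <- data.frame(
          gene_id = g, stage = sample(11:16, 1),
          term = sample(terms_late, 1))
      do.call(rbind, out)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$term <- as.character(out$term)
    out
  })
}

#' Generate a reference TSS-enrichment ranking
#'
#' Stands in for an external late-embryo (6-8 hr muscle) Pol II dataset used
#' to separate pre-MBT 'dual' genes: transcripts of planted dual genes are
#' given top-20% reference percentiles, everything else falls below 0.8.
#'
#' @param plan A [simulation_plan()].
#' @param truth Ground truth from [generate_annotation()].
#' @param annotation Transcript annotation.
#' @return Data frame: transcript_id, percentile.
#' @export
generate_reference_ranking <- function(plan, truth, annotation) {
  with_seed(derive_seed(plan$seed, "reference"), {
    grp <- truth$genes$group[match(annotation$gene_id, truth$genes$gene_id)]
    dual <- grp == "pre-MBT dual"
    data.frame(transcript_id = annotation$transcript_id,
               percentile = round(ifelse(dual, runif(nrow(annotation), 0.85, 1),
                                         runif(nrow(annotation), 0, 0.8)), 4),
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic TBP peak set
#'
#' One peak per Pol II-bound gene, centered on the primary TSS with the
#' summit 20 bp upstream of it (TBP sits upstream of the start site).
#'
#' @param plan A [simulation_plan()].
#' @param truth Ground truth from [generate_annotation()].
#' @param halfwidth Peak half-width in bp.
#' @return Data frame: chrom, start, end, summit.
#' @export
generate_tbp_peaks <- function(plan, truth, halfwidth = 150L) {
  genes <- truth$genes[truth$genes$group %in% bound_groups(), , drop = FALSE]
  if (nrow(genes) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), summit = integer(),
                      stringsAsFactors = FALSE))
  dir <- ifelse(genes$strand == "+", 1L, -1L)
  summit <- genes$tss - 20L * dir
  data.frame(chrom = genes$chrom,
             start = pmax(0L, summit - as.integer(halfwidth)),
             end = summit + as.integer(halfwidth),
             summit = summit, stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper producing every pipeline input for the default study
#' design: four pre-MBT and three MBT IP/WCE replicate pairs, annotation,
#' expression table, promoters, conservation track, pattern annotations,
#' reference ranking and TBP peaks.
#'
#' @param plan A [simulation_plan()].
#' @param n_pre_replicates,n_mbt_replicates Replicates per stage.
#' @return List with all inputs plus the ground truth.
#' @export
simulate_study <- function(plan, n_pre_replicates = 4, n_mbt_replicates = 3) {
  ann <- generate_annotation(plan)
  truth <- ann$truth
  pre_reps <- lapply(seq_len(n_pre_replicates), function(r)
    simulate_reads(plan, truth, "pre-MBT", r))
  mbt_reps <- lapply(seq_len(n_mbt_replicates), function(r)
    simulate_reads(plan, truth, "MBT", r))
  promoters <- generate_promoters(plan, truth, ann$transcripts)
  truth$motifs <- promoters$plants
  list(plan = plan,
       transcripts = ann$transcripts,
       truth = truth,
       pre_replicates = pre_reps,
       mbt_replicates = mbt_reps,
       expression = generate_expression(plan, truth),
       promoters = promoters,
       conservation = generate_score_track(plan, truth),
       patterns = generate_pattern_annotations(plan, truth),
       reference_ranking = generate_reference_ranking(plan, truth,
                                                      ann$transcripts),
       tbp_peaks = generate_tbp_peaks(plan, truth))
}
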
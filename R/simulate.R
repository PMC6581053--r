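#' Simulation configuration
#'
#' Parameters of the synthetic sorted-embryo RNA-seq design. Defaults mirror
#' the study design the pipeline targets: seven tissues sampled at five
#' 90-minute time points with two biological replicates (three for ABa, four
#' for muscle) and a matched unlabeled sort per tissue/time point.
#'
#' @param seed Integer seed; every generator is fully deterministic given the
#'   config.
#' @param n_genes,n_operons Number of genes and of operons (2-4 members each).
#' @param tissues Character vector of tissue names.
#' @param n_times Number of time points.
#' @param replicates Either a single integer or a named vector of per-tissue
#'   replicate counts; unnamed tissues fall back to the `.default` entry.
#'   `NULL` means the study design (muscle 4, ABa 3, others 2).
#' @param unlabeled Generate one matched unlabeled sample per (tissue, time)?
#' @param program_mix Named fractions of expression programs among coding,
#'   non-operon genes: `maternal` (decaying everywhere), `zygotic` (broad
#'   logistic rise), `tissue_specific` (rise in one tissue), `stable`
#'   (constant), `switch` (tissue A early, tissue B late). Must sum to 1.
#' @param nb_dispersion Negative-binomial dispersion of counts around the
#'   library-scaled means (`0` gives Poisson).
#' @param dup_rate Overall PCR duplicate fraction in `[0, 1)`.
#' @param hh_share Probability that a head-to-head (divergently transcribed)
#'   gene pair shares its program, emulating a shared bidirectional
#'   regulatory region.
#' @param sl_gene_fraction Fraction of monocistronic genes carrying an SL
#'   (trans-splice) site.
#' @param edit_sites Number of true A-to-G edit sites to inject.
#' @param tf_count Number of simulated transcription factors.
#' @param peak_enrichment_odds Odds of a promoter peak for a TF's target-tissue
#'   genes relative to background genes.
#' @param lib_size_mean,lib_size_sd_log Per-sample library size: log-normal
#'   with this mean (fragment pairs) and log-sd. The real study averages 12
#'   million pairs per sample; the default emulates that depth in proportion
#'   at desk scale.
#' @param frag_len_mean,frag_len_sd Fragment length distribution (bp). The
#'   near-fixed default length shrinks the fragment coordinate space so
#'   that, at desk-scale depth, highly expressed genes saturate it the way
#'   they do in full-depth libraries (the regime the duplicate estimator
#'   exists for).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_genes = 600, n_operons = 30,
                       tissues = default_tissues(), n_times = 5,
                       replicates = NULL, unlabeled = TRUE,
                       program_mix = c(maternal = 0.20, zygotic = 0.25,
                                       tissue_specific = 0.30, stable = 0.20,
                                       switch = 0.05),
                       nb_dispersion = 0.05, dup_rate = 0.25,
                       hh_share = 0.7,
                       sl_gene_fraction = 0.7, edit_sites = 12,
                       tf_count = 5, peak_enrichment_odds = 10,
                       lib_size_mean = 1.2e5, lib_size_sd_log = 0.2,
                       frag_len_mean = 250, frag_len_sd = 1) {
  if (abs(sum(program_mix) - 1) > 1e-8) {
    rlang::abort("program_mix fractions must sum to 1")
  }
  if (dup_rate < 0 || dup_rate >= 1) rlang::abort("dup_rate must be in [0, 1)")
  if (n_genes < 4 * n_operons + 10) {
    rlang::abort("n_genes too small to place n_operons operons")
  }
  if (is.null(replicates)) {
    replicates <- c(muscle = 4, ABa = 3, .default = 2)
  }
  cfg <- list(seed = as.integer(seed), n_genes = n_genes,
              n_operons = n_operons, tissues = tissues, n_times = n_times,
              replicates = replicates, unlabeled = unlabeled,
              program_mix = program_mix, nb_dispersion = nb_dispersion,
              dup_rate = dup_rate, hh_share = hh_share,
              sl_gene_fraction = sl_gene_fraction,
              edit_sites = edit_sites, tf_count = tf_count,
              peak_enrichment_odds = peak_enrichment_odds,
              lib_size_mean = lib_size_mean, lib_size_sd_log = lib_size_sd_log,
              frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd)
  structure(cfg, class = "sim_config")
}

replicates_for <- function(cfg) {
  r <- cfg$replicates
  if (length(r) == 1 && is.null(names(r))) {
    return(stats::setNames(rep(as.integer(r), length(cfg$tissues)), cfg$tissues))
  }
  default <- if (".default" %in% names(r)) r[[".default"]] else 2L
  out <- vapply(cfg$tissues, function(t) {
    as.integer(if (t %in% names(r)) r[[t]] else default)
  }, integer(1))
  out
}

#' Sample sheet for a simulation config
#'
#' @param cfg A [sim_config()].
#' @return Tibble `sample`, `tissue`, `time`, `rep`, `labeled` covering all
#'   labeled replicates plus matched unlabeled sorts (rep 1).
#' @export
sim_samples <- function(cfg) {
  reps <- replicates_for(cfg)
  lab <- purrr::map_dfr(cfg$tissues, function(t) {
    tidyr::expand_grid(tissue = t, time = 0:(cfg$n_times - 1),
                       rep = seq_len(reps[[t]]), labeled = TRUE)
  })
  if (cfg$unlabeled) {
    unl <- tidyr::expand_grid(tissue = cfg$tissues,
                              time = 0:(cfg$n_times - 1), rep = 1L,
                              labeled = FALSE)
    lab <- dplyr::bind_rows(lab, unl)
  }
  dplyr::mutate(lab,
                sample = format_sample_key(.data$tissue, .data$time,
                                           .data$rep, .data$labeled),
                .before = 1)
}

#' Generate a synthetic genome annotation
#'
#' Places `n_genes` multi-exon genes on two chromosomes with random
#' orientations (so head-to-head, head-to-tail and tail-to-tail adjacencies
#' all occur), inserts `n_operons` operons of 2-4 consecutive same-strand
#' genes with short intergenic gaps, and flags ~2% of non-operon genes as
#' histone and ~1% as rRNA.
#'
#' @param cfg A [sim_config()].
#' @return A `genome_annotation`.
#' @export
sim_annotation <- function(cfg) {
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    op_sizes <- if (cfg$n_operons > 0) {
      sample(2:4, cfg$n_operons, replace = TRUE)
    } else integer()
    # lay genes out as shuffled blocks: each operon is one block of 2-4
    # consecutive same-strand genes, every other gene is a singleton block;
    # blocks never straddle the chromosome split, so operons stay intact
    n_single <- n - sum(op_sizes)
    block_size <- sample(c(op_sizes, rep(1L, n_single)))
    block_op <- integer(length(block_size))
    block_op[block_size > 1] <- seq_len(sum(block_size > 1))
    block_chrom <- ifelse(cumsum(block_size) <= ceiling(n / 2), "chrI", "chrII")
    genes <- vector("list", n)
    operon_of <- rep(NA_character_, n)
    operon_pos <- rep(NA_integer_, n)
    cursor <- c(chrI = 1000L, chrII = 1000L)
    i <- 0L
    for (b in seq_along(block_size)) {
      chrom <- block_chrom[b]
      strand <- sample(c("+", "-"), 1)
      sz <- block_size[b]
      for (j in seq_len(sz)) {
        i <- i + 1L
        gap <- if (j == 1) sample(200:2000, 1) else sample(80:200, 1)
        n_ex <- sample(2:6, 1)
        ex_len <- sample(100:400, n_ex, replace = TRUE)
        in_len <- if (n_ex > 1) sample(50:300, n_ex - 1, replace = TRUE) else integer()
        g_start <- cursor[[chrom]] + gap
        ex_start <- g_start + c(0L, cumsum(ex_len[-n_ex] + in_len))
        ex_end <- ex_start + ex_len
        g_end <- max(ex_end)
        cursor[[chrom]] <- g_end
        gid <- sprintf("gene%04d", i)
        if (sz > 1) {
          operon_of[i] <- sprintf("oper%03d", block_op[b])
          # 5'->3' in transcription direction: on '-' the first member is
          # the rightmost gene
          operon_pos[i] <- if (strand == "+") j else sz - j + 1L
        }
        genes[[i]] <- tibble::tibble(
          gene_id = gid, chrom = chrom, strand = strand,
          start = g_start, end = g_end,
          exons = list(tibble::tibble(gene_id = gid, start = ex_start,
                                      end = ex_end)))
      }
    }
    gtab <- dplyr::bind_rows(genes)
    ops <- tibble::tibble(operon_id = operon_of, gene_id = gtab$gene_id,
                          position = operon_pos) |>
      dplyr::filter(!is.na(.data$operon_id))
    biotype <- rep("coding", n)
    free <- which(!gtab$gene_id %in% ops$gene_id)
    n_his <- max(1L, round(0.02 * n))
    n_rrna <- max(1L, round(0.01 * n))
    marked <- sample(free, n_his + n_rrna)
    biotype[marked[seq_len(n_his)]] <- "histone"
    biotype[marked[n_his + seq_len(n_rrna)]] <- "rRNA"
    gtab$biotype <- biotype
    exons <- dplyr::bind_rows(gtab$exons)
    genome_annotation(
      genes = dplyr::select(gtab, -"exons"),
      exons = exons,
      operons = if (nrow(ops)) ops else NULL,
      chrom_lengths = cursor + 5000L
    )
  })
}

# internal-promoter strength of downstream operon genes, in [0, 1];
# deterministic per config so expression and SL generators agree
sim_promoter_strengths <- function(cfg, ann) {
  down <- downstream_operon_genes(ann)
  with_seed(cfg$seed + 101L, {
    tibble::tibble(gene_id = down,
                   promoter_strength = stats::runif(length(down)))
  })
}

# program shape over time, per program label; returns tissue x time mean-TPM
program_shape <- function(program, tissues, n_times, baseline, tissue_a,
                          tissue_b, leak_dir = 1) {
  t <- seq_len(n_times) - 1
  # off-target leakage of restricted programs drifts over time (direction
  # gene-specific) rather than sitting flat, as residual sorting
  # contamination does; gene-specific directions survive the compositional
  # TPM renormalization where a shared drift would cancel
  leak <- 0.25 + 0.45 * (if (leak_dir >= 0) t else rev(t))
  m <- matrix(0, length(tissues), n_times, dimnames = list(tissues, NULL))
  switch(program,
    maternal = m[] <- rep(baseline * 0.5^t, each = length(tissues)),
    zygotic = m[] <- rep(baseline * 2 * stats::plogis((t - 2) / 0.7),
                         each = length(tissues)),
    stable = m[] <- baseline,
    tissue_specific = {
      m[] <- rep(baseline * 0.05 * leak, each = length(tissues))
      m[tissue_a, ] <- baseline * 5 * (0.15 + stats::plogis((t - 1.5) / 0.7))
    },
    switch = {
      m[] <- rep(baseline * 0.05 * leak, each = length(tissues))
      m[tissue_a, ] <- baseline * 5 * rev(stats::plogis((t - 2) / 0.5))
      m[tissue_b, ] <- baseline * 5 * stats::plogis((t - 2) / 0.5)
    },
    histone = m[] <- rep(baseline * 20 * 0.6^t, each = length(tissues)),
    rRNA = m[] <- baseline * 40
  )
  m
}

#' Assign expression programs and true mean TPM
#'
#' Assigns each gene an expression program (maternal decay, broad zygotic
#' rise, tissue-specific rise, stable, or tissue switch) and builds the
#' noiseless mean-TPM surface over (tissue, time). Operon members share the
#' first gene's program (operons lean housekeeping: stable-biased, tight
#' baseline range); a downstream member with internal-promoter strength `s`
#' is a fixed read-through fraction of the first gene's profile plus an
#' `s`-scaled independent profile, so its expression and its distance to
#' the upstream gene both grow with `s`. Head-to-head neighbors share their
#' program with probability `hh_share`. Histone genes are highly expressed
#' early and decay; rRNA genes are high and flat (both are excluded again
#' at TPM time).
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation from [sim_annotation()].
#' @return List with `truth` (per-gene program table) and `true_tpm` (long
#'   tibble of noiseless mean TPM per gene, tissue, time; included genes
#'   sum to 1e6 per condition).
#' @export
sim_programs <- function(cfg, ann) {
  with_seed(cfg$seed + 1L, {
    genes <- ann$genes
    n <- nrow(genes)
    tissues <- cfg$tissues
    programs <- names(cfg$program_mix)
    first_of_op <- ann$operons$gene_id[ann$operons$position == 1]
    down <- downstream_operon_genes(ann)
    assignable <- genes$biotype == "coding" & !genes$gene_id %in% down
    prog <- rep(NA_character_, n)
    prog[assignable] <- sample(programs, sum(assignable), replace = TRUE,
                               prob = cfg$program_mix)
    prog[genes$biotype == "histone"] <- "histone"
    prog[genes$biotype == "rRNA"] <- "rRNA"
    baseline <- stats::rlnorm(n, meanlog = log(30), sdlog = 1)
    tissue_a <- sample(tissues, n, replace = TRUE)
    rel <- related_tissue_matrix(tissues)
    tissue_b <- vapply(tissue_a, function(a) {
      pool <- tissues[!rel[a, tissues]]
      if (length(pool) == 0) pool <- setdiff(tissues, a)
      sample(pool, 1)
    }, character(1))
    # operon genes: housekeeping-like — stable-biased programs and a tight
    # baseline range; downstream members inherit the first member's program
    op_first <- ann$operons |>
      dplyr::filter(.data$position == 1) |>
      dplyr::select("operon_id", first_gene = "gene_id")
    op_map <- ann$operons |>
      dplyr::left_join(op_first, by = "operon_id")
    idx <- stats::setNames(seq_len(n), genes$gene_id)
    firsts <- idx[unique(op_map$first_gene)]
    op_bias <- c(maternal = 0.10, zygotic = 0.15, tissue_specific = 0.10,
                 stable = 0.60, switch = 0.05)[programs]
    op_probs <- dplyr::coalesce(unname(op_bias), cfg$program_mix)
    prog[firsts] <- sample(programs, length(firsts), replace = TRUE,
                           prob = op_probs)
    baseline[firsts] <- stats::rlnorm(length(firsts), log(60), 0.3)
    for (r in seq_len(nrow(op_map))) {
      gi <- idx[[op_map$gene_id[r]]]
      fi <- idx[[op_map$first_gene[r]]]
      prog[gi] <- prog[fi]
      tissue_a[gi] <- tissue_a[fi]
      tissue_b[gi] <- tissue_b[fi]
      if (op_map$position[r] > 1) baseline[gi] <- baseline[fi]
    }
    # head-to-head neighbors share a bidirectional regulatory region: the
    # downstream-of-promoter partner inherits the program with probability
    # hh_share
    ordg <- dplyr::arrange(genes, .data$chrom, .data$start)
    nbr_same_chrom <- ordg$chrom[-1] == ordg$chrom[-nrow(ordg)]
    hh <- which(nbr_same_chrom & ordg$strand[-nrow(ordg)] == "-" &
                  ordg$strand[-1] == "+")
    in_op <- ordg$gene_id %in% ann$operons$gene_id
    coding <- ordg$biotype == "coding"
    hh <- hh[!in_op[hh] & !in_op[hh + 1] & coding[hh] & coding[hh + 1]]
    for (h in hh) {
      if (stats::runif(1) < cfg$hh_share) {
        gi <- idx[[ordg$gene_id[h + 1]]]
        fi <- idx[[ordg$gene_id[h]]]
        prog[gi] <- prog[fi]
        tissue_a[gi] <- tissue_a[fi]
        tissue_b[gi] <- tissue_b[fi]
        baseline[gi] <- baseline[fi] * stats::rlnorm(1, 0, 0.2)
      }
    }
    strengths <- sim_promoter_strengths(cfg, ann)
    smap <- stats::setNames(strengths$promoter_strength, strengths$gene_id)
    # independent profile mixed into downstream genes with internal promoters
    ind_tissue <- vapply(tissue_a, function(a) sample(setdiff(tissues, a), 1),
                         character(1))
    leak_dir <- sample(c(1, -1), n, replace = TRUE)
    mean_list <- purrr::map(seq_len(n), function(i) {
      m <- program_shape(prog[i], tissues, cfg$n_times, baseline[i],
                         tissue_a[i], tissue_b[i], leak_dir[i])
      g <- genes$gene_id[i]
      if (g %in% names(smap)) {
        # downstream operon mRNA = polycistronic read-through (a fixed
        # fraction of the first gene's profile) plus the gene's own
        # internal promoter, whose output scales with its strength and
        # initiates with SL1
        s <- smap[[g]]
        ind <- program_shape("tissue_specific", tissues, cfg$n_times,
                             0.4 * baseline[i], ind_tissue[i], tissue_b[i],
                             leak_dir[i])
        m <- 0.7 * m + s * ind
      }
      m
    })
    true_tpm <- purrr::imap_dfr(mean_list, function(m, i) {
      tibble::tibble(gene_id = genes$gene_id[i],
                     tissue = rep(tissues, cfg$n_times),
                     time = rep(0:(cfg$n_times - 1), each = length(tissues)),
                     true_tpm = as.vector(m))
    })
    # rescale so included (non-histone/rRNA) genes sum to 1e6 per condition
    excl <- genes$gene_id[genes$biotype %in% c("histone", "rRNA")]
    true_tpm <- true_tpm |>
      dplyr::group_by(.data$tissue, .data$time) |>
      dplyr::mutate(true_tpm = .data$true_tpm * 1e6 /
                      sum(.data$true_tpm[!.data$gene_id %in% excl])) |>
      dplyr::ungroup()
    truth <- tibble::tibble(gene_id = genes$gene_id, program = prog,
                            baseline = baseline, tissue_a = tissue_a,
                            tissue_b = tissue_b) |>
      dplyr::left_join(strengths, by = "gene_id")
    list(truth = truth, true_tpm = true_tpm)
  })
}

#' Generate a count matrix around the true expression surface
#'
#' Draws negative-binomial counts with dispersion `cfg$nb_dispersion`
#' around library-size-scaled means for every sample of the design
#' ([sim_samples()]). Unlabeled samples get the across-tissue mean profile
#' (a whole-embryo mixture).
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation from [sim_annotation()].
#' @param programs Optional result of [sim_programs()] (recomputed when
#'   `NULL`).
#' @return List with `counts` (long tibble: `gene_id`, `sample`, `tissue`,
#'   `time`, `rep`, `labeled`, `count`), `truth`, and `true_tpm`.
#' @export
sim_expression <- function(cfg, ann, programs = NULL) {
  programs <- programs %||% sim_programs(cfg, ann)
  true_tpm <- programs$true_tpm
  genes <- ann$genes
  n <- nrow(genes)
  counts <- with_seed(cfg$seed + 6L, {
    samples <- sim_samples(cfg)
    lens <- gene_lengths(ann)
    lmap <- stats::setNames(lens$length, lens$gene_id)
    lib <- stats::rlnorm(nrow(samples), log(cfg$lib_size_mean),
                         cfg$lib_size_sd_log)
    # unlabeled sorts approximate the whole-embryo mixture at that time
    unl_tpm <- true_tpm |>
      dplyr::group_by(.data$gene_id, .data$time) |>
      dplyr::summarise(true_tpm = mean(.data$true_tpm), .groups = "drop")
    purrr::map_dfr(seq_len(nrow(samples)), function(si) {
      s <- samples[si, ]
      tp <- if (s$labeled) {
        dplyr::filter(true_tpm, .data$tissue == s$tissue,
                      .data$time == s$time)
      } else {
        dplyr::filter(unl_tpm, .data$time == s$time)
      }
      tp <- tp[match(genes$gene_id, tp$gene_id), ]
      w <- tp$true_tpm * lmap[genes$gene_id]
      mu <- w / sum(w) * lib[si]
      cnt <- if (cfg$nb_dispersion <= 0) {
        stats::rpois(n, mu)
      } else {
        stats::rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
      }
      tibble::tibble(gene_id = genes$gene_id, sample = s$sample,
                     tissue = s$tissue, time = s$time, rep = s$rep,
                     labeled = s$labeled, count = cnt)
    })
  })
  list(counts = counts, truth = programs$truth, true_tpm = true_tpm)
}

#' Generate aligned fragments with a PCR-duplication process
#'
#' For one sample, unique fragments are placed uniformly over gene bodies
#' with per-gene abundance proportional to expression; each unique fragment
#' is then amplified `k` extra times with `k ~ Geometric(1 - dup_rate)`, so
#' the expected duplicate fraction equals `dup_rate`. PCR duplicates share
#' exact (chrom, strand, start, end); natural coordinate collisions between
#' distinct molecules arise in highly expressed genes.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation.
#' @param n_fragments Target total fragment count (unique + duplicates).
#' @param sample Sample key to stamp on the records.
#' @param gene_weights Optional named per-gene abundance weights; defaults to
#'   a heavy-tailed log-normal draw so that high-coverage genes exist.
#' @return Tibble of fragments with truth columns `gene_id`, `molecule`
#'   (unique-molecule id) and `is_pcr_duplicate`.
#' @export
sim_fragments <- function(cfg, ann, n_fragments = 1e5,
                          sample = "muscle:0:1", gene_weights = NULL) {
  with_seed(cfg$seed + 2L, {
    genes <- ann$genes
    if (is.null(gene_weights)) {
      # heavy tail: a handful of very deep genes, as in embryonic libraries
      gene_weights <- stats::setNames(stats::rlnorm(nrow(genes), 0, 2.5),
                                      genes$gene_id)
    }
    w <- gene_weights[genes$gene_id]
    n_unique <- round(n_fragments * (1 - cfg$dup_rate))
    gi <- sample.int(nrow(genes), n_unique, replace = TRUE, prob = w)
    len <- pmax(50L, round(stats::rnorm(n_unique, cfg$frag_len_mean,
                                        cfg$frag_len_sd)))
    glen <- genes$end[gi] - genes$start[gi]
    len <- pmin(len, glen)
    start <- genes$start[gi] +
      floor(stats::runif(n_unique) * (glen - len + 1))
    uniq <- tibble::tibble(
      sample = sample, chrom = genes$chrom[gi], strand = genes$strand[gi],
      start = as.integer(start), end = as.integer(start + len),
      gene_id = genes$gene_id[gi],
      molecule = seq_len(n_unique), is_pcr_duplicate = FALSE)
    k <- stats::rgeom(n_unique, prob = 1 - cfg$dup_rate)
    dup_idx <- rep.int(seq_len(n_unique), k)
    dups <- uniq[dup_idx, ]
    dups$is_pcr_duplicate <- TRUE
    out <- dplyr::bind_rows(uniq, dups) |>
      dplyr::arrange(.data$chrom, .data$start, .data$end)
    out$read_id <- sprintf("r%07d", seq_len(nrow(out)))
    dplyr::relocate(out, "read_id", .after = "end")
  })
}

#' Generate SL1/SL2 splice-leader read counts per acceptor site
#'
#' First operon genes and a configured fraction of monocistronic genes get
#' SL1-dominant sites (SL1 marks transcript initiation); downstream operon
#' genes get SL2-dominant sites whose SL1 admixture equals the gene's
#' internal-promoter strength, reflecting independent transcription
#' initiation at the downstream gene.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation.
#' @param mono_sl2_admixture SL2 fraction at monocistronic/first-gene sites
#'   (default 0: pure SL1).
#' @return Tibble `gene_id`, `chrom`, `acceptor`, `sl1`, `sl2`,
#'   `true_class`, `promoter_strength`.
#' @export
sim_sl_reads <- function(cfg, ann, mono_sl2_admixture = 0) {
  with_seed(cfg$seed + 3L, {
    genes <- gene_promoters(ann)
    first_of_op <- ann$operons$gene_id[ann$operons$position == 1]
    down <- downstream_operon_genes(ann)
    mono <- setdiff(genes$gene_id[genes$biotype == "coding"],
                    c(first_of_op, down))
    mono_sl <- sample(mono, round(cfg$sl_gene_fraction * length(mono)))
    strengths <- sim_promoter_strengths(cfg, ann)
    smap <- stats::setNames(strengths$promoter_strength, strengths$gene_id)
    make_site <- function(gid, sl1_frac, true_class, strength = NA_real_) {
      g <- genes[genes$gene_id == gid, ]
      total <- stats::rpois(1, 30) + 5L
      sl1 <- stats::rbinom(1, total, sl1_frac)
      tibble::tibble(gene_id = gid, chrom = g$chrom, acceptor = g$tss,
                     sl1 = sl1, sl2 = total - sl1, true_class = true_class,
                     promoter_strength = strength)
    }
    sl1_sites <- purrr::map_dfr(c(first_of_op, mono_sl), make_site,
                                sl1_frac = 1 - mono_sl2_admixture,
                                true_class = "SL1")
    sl2_sites <- purrr::map_dfr(down, function(gid) {
      s <- smap[[gid]]
      make_site(gid, sl1_frac = s, true_class = "SL2", strength = s)
    })
    dplyr::bind_rows(sl1_sites, sl2_sites)
  })
}

#' Generate ChIP-seq peaks enriched at target-gene promoters
#'
#' Each simulated TF is assigned a target tissue; its peaks fall in the
#' promoters of that tissue's specific genes with odds
#' `peak_enrichment_odds` relative to background genes. Independently,
#' downstream operon genes accumulate a cluster of peaks (from
#' `cluster_tfs` distinct TFs) with probability equal to their
#' internal-promoter strength, emulating independent promoters marked by TF
#' binding.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation.
#' @param truth Truth table from [sim_expression()] (for tissue-specific
#'   target genes). May be `NULL`, in which case targets are drawn at random.
#' @param background_rate Peak probability at non-target promoters.
#' @param cluster_tfs Number of distinct TFs in an operon-downstream peak
#'   cluster (0 disables that component).
#' @return List with `peaks` (tibble `tf`, `chrom`, `start`, `end`) and
#'   `tf_truth` (tibble `tf`, `target_tissue`).
#' @export
sim_peaks <- function(cfg, ann, truth = NULL, background_rate = 0.1,
                      cluster_tfs = 3) {
  with_seed(cfg$seed + 4L, {
    if (cfg$tf_count == 0) {
      return(list(peaks = tibble::tibble(tf = character(), chrom = character(),
                                         start = integer(), end = integer()),
                  tf_truth = tibble::tibble(tf = character(),
                                            target_tissue = character())))
    }
    proms <- gene_promoters(ann)
    tfs <- sprintf("tf%02d", seq_len(cfg$tf_count))
    target_tissue <- rep(cfg$tissues, length.out = cfg$tf_count)
    odds <- cfg$peak_enrichment_odds
    p0 <- background_rate
    p1 <- odds * p0 / (1 - p0 + odds * p0)
    peak_at <- function(g, tf) {
      center <- floor((g$prom_start + g$prom_end) / 2)
      tibble::tibble(tf = tf, chrom = g$chrom,
                     start = pmax(0, center - 100L), end = center + 100L)
    }
    peaks <- purrr::map_dfr(seq_along(tfs), function(i) {
      targets <- if (!is.null(truth)) {
        truth$gene_id[truth$program %in% "tissue_specific" &
                        truth$tissue_a == target_tissue[i]]
      } else {
        sample(proms$gene_id, max(1, round(nrow(proms) * 0.1)))
      }
      p <- ifelse(proms$gene_id %in% targets, p1, p0)
      hit <- stats::runif(nrow(proms)) < p
      peak_at(proms[hit, ], tfs[i])
    })
    if (cluster_tfs > 0 && cfg$tf_count >= cluster_tfs) {
      strengths <- sim_promoter_strengths(cfg, ann)
      hit <- strengths$gene_id[stats::runif(nrow(strengths)) <
                                 strengths$promoter_strength]
      cl <- purrr::map_dfr(hit, function(gid) {
        g <- proms[proms$gene_id == gid, ]
        purrr::map_dfr(sample(tfs, cluster_tfs), function(tf) peak_at(g, tf))
      })
      peaks <- dplyr::bind_rows(peaks, cl)
    }
    list(peaks = dplyr::arrange(peaks, .data$chrom, .data$start),
         tf_truth = tibble::tibble(tf = tfs, target_tissue = target_tissue))
  })
}

#' Generate pileup base counts with injected A-to-G edit sites
#'
#' Injects `cfg$edit_sites` true A-to-G edits (observed as T-to-C in
#' reference coordinates for minus-strand genes) inside coding exons. True
#' sites carry alternate reads in three labeled samples and none in
#' unlabeled samples; decoy sites (genomic-variant mimics) are altered in
#' unlabeled samples too; singleton sites are altered in exactly one labeled
#' sample; a couple of non-A-to-G mismatch sites exercise the
#' mismatch-class filter.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation.
#' @param edit_fraction Mean alternate-allele fraction at edited positions.
#' @return List with `pileups` (tibble `chrom`, `pos`, `ref`, `sample`, `A`,
#'   `C`, `G`, `T`) and `truth` (tibble `chrom`, `pos`, `gene_id`, `class`).
#' @export
sim_pileups <- function(cfg, ann, edit_fraction = 0.4) {
  with_seed(cfg$seed + 5L, {
    samples <- sim_samples(cfg)
    cds_genes <- unique(ann$cds$gene_id)
    n_decoy <- max(2L, round(cfg$edit_sites / 3))
    n_single <- max(2L, round(cfg$edit_sites / 3))
    n_other <- 2L
    n_sites <- cfg$edit_sites + n_decoy + n_single + n_other
    gids <- sample(cds_genes, n_sites, replace = TRUE)
    classes <- c(rep("true", cfg$edit_sites), rep("decoy", n_decoy),
                 rep("singleton", n_single), rep("other_mismatch", n_other))
    gmap <- stats::setNames(ann$genes$strand, ann$genes$gene_id)
    sites <- purrr::map_dfr(seq_len(n_sites), function(i) {
      cds <- ann$cds[ann$cds$gene_id == gids[i], ]
      row <- cds[sample.int(nrow(cds), 1), ]
      pos <- row$start + sample.int(row$end - row$start, 1) - 1L
      strand <- gmap[[gids[i]]]
      if (classes[i] == "other_mismatch") {
        ref <- if (strand == "+") "C" else "G"
        alt <- if (strand == "+") "T" else "A"
      } else {
        ref <- if (strand == "+") "A" else "T"
        alt <- if (strand == "+") "G" else "C"
      }
      tibble::tibble(chrom = ann$genes$chrom[ann$genes$gene_id == gids[i]],
                     pos = pos, gene_id = gids[i], strand = strand,
                     ref = ref, alt = alt, class = classes[i])
    })
    # guard against coordinate collisions between sites
    sites <- dplyr::distinct(sites, .data$chrom, .data$pos, .keep_all = TRUE)
    lab <- samples$sample[samples$labeled]
    unl <- samples$sample[!samples$labeled]
    pileups <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
      st <- sites[i, ]
      edited_lab <- sample(lab, if (st$class == "singleton") 1 else 3)
      edited_unl <- if (st$class == "decoy") sample(unl, 2) else character()
      use <- unique(c(edited_lab, edited_unl, sample(lab, 3), sample(unl, 1)))
      purrr::map_dfr(use, function(smp) {
        cov <- 20L + stats::rpois(1, 15)
        alt_n <- if (smp %in% c(edited_lab, edited_unl)) {
          stats::rbinom(1, cov, edit_fraction)
        } else 0L
        counts <- stats::setNames(c(0L, 0L, 0L, 0L), c("A", "C", "G", "T"))
        counts[st$ref] <- cov - alt_n
        counts[st$alt] <- alt_n
        tibble::tibble(chrom = st$chrom, pos = st$pos, ref = st$ref,
                       sample = smp, A = counts[["A"]], C = counts[["C"]],
                       G = counts[["G"]], T = counts[["T"]])
      })
    })
    list(pileups = pileups,
         truth = dplyr::select(sites, "chrom", "pos", "gene_id", "strand",
                               "class"))
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs every generator under one config and returns all pieces; the
#' ground-truth tables make each downstream stage testable.
#'
#' @param cfg A [sim_config()].
#' @param n_fragments Fragments for the single fragment library (see
#'   [sim_fragments()]).
#' @return Named list: `ann`, `counts`, `truth`, `true_tpm`, `fragments`,
#'   `sl`, `peaks`, `tf_truth`, `pileups`, `pileup_truth`.
#' @export
simulate_dataset <- function(cfg = sim_config(), n_fragments = 2e4) {
  ann <- sim_annotation(cfg)
  expr <- sim_expression(cfg, ann)
  frags <- sim_fragments(cfg, ann, n_fragments = n_fragments)
  sl <- sim_sl_reads(cfg, ann)
  pk <- sim_peaks(cfg, ann, truth = expr$truth)
  pe <- sim_pileups(cfg, ann)
  list(ann = ann, counts = expr$counts, truth = expr$truth,
       true_tpm = expr$true_tpm, fragments = frags, sl = sl,
       peaks = pk$peaks, tf_truth = pk$tf_truth, pileups = pe$pileups,
       pileup_truth = pe$truth)
}
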
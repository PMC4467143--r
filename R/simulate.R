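# Synthetic-data generators with known planted truths. They emulate the three
# study designs the pipeline consumes: a 470-miRNA dual-luciferase reporter
# screen replicated twice with analog screens for centering, a MYCN
# non-amplified tumor cohort with miRNA/mRNA expression, and a murine
# genotype x time qPCR Cq time course.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop("`", name, "` must be an integer >= ", min)
  }
  as.integer(x)
}

#' Configuration for the synthetic reporter screen
#'
#' @param n_mirnas Number of miRNAs in the mimic library (default 470).
#' @param n_targeting Number of miRNAs with a planted repression effect on the
#'   focal reporter (default 29).
#' @param effect_log2 Planted mean shift of the log2 Firefly/Renilla ratio for
#'   targeting miRNAs; negative = repression (default -3).
#' @param noise_sd Standard deviation of additive Gaussian noise on the log2
#'   ratio (default 0.3).
#' @param n_replicates Independent focal-screen replicates (default 2).
#' @param n_analog_screens Analog screens of unrelated 3'UTRs used for
#'   per-miRNA median centering (default 36); they carry no focal effect.
#' @param bias_sd Standard deviation of a per-miRNA bias shared by all screens
#'   (focal and analog); default 0. Non-zero values exercise the centering
#'   step, which removes exactly this kind of systematic bias.
#' @param seed Integer seed.
#' @return A list of class `"screen_sim_config"`.
#' @export
screen_sim_config <- function(n_mirnas = 470, n_targeting = 29,
                              effect_log2 = -3, noise_sd = 0.3,
                              n_replicates = 2, n_analog_screens = 36,
                              bias_sd = 0, seed = 1) {
  n_mirnas <- check_count(n_mirnas, "n_mirnas")
  n_targeting <- check_count(n_targeting, "n_targeting", min = 0L)
  n_replicates <- check_count(n_replicates, "n_replicates")
  n_analog_screens <- check_count(n_analog_screens, "n_analog_screens")
  if (n_targeting > n_mirnas) stop("n_targeting must not exceed n_mirnas")
  if (noise_sd < 0 || bias_sd < 0) stop("noise_sd and bias_sd must be >= 0")
  structure(
    list(n_mirnas = n_mirnas, n_targeting = n_targeting,
         effect_log2 = effect_log2, noise_sd = noise_sd,
         n_replicates = n_replicates, n_analog_screens = n_analog_screens,
         bias_sd = bias_sd, seed = seed),
    class = "screen_sim_config"
  )
}

#' Simulate a dual-luciferase reporter screen
#'
#' Renilla readings are fixed at 1000; Firefly readings are
#' `1000 * 2^(bias + effect + noise)` where the planted effect applies only to
#' targeting miRNAs in the focal screen. Analog screens contain bias and noise
#' but no focal effect, so the per-miRNA analog median isolates the planted
#' repression.
#'
#' @param config A [screen_sim_config()].
#' @return A list with `plates` (the `ScreenPlateTable` data frame covering
#'   the focal `"MYCN"` screen and all analog screens) and `truth` (data frame
#'   `mirna_id`, `targeting`).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  with_seed(config$seed, {
    ids <- sprintf("miR-%03d", seq_len(config$n_mirnas))
    targeting <- sort(sample(ids, config$n_targeting))
    bias <- stats::rnorm(config$n_mirnas, 0, config$bias_sd)
    names(bias) <- ids

    make_rows <- function(screen_id, replicate, effect) {
      log_ratio <- bias + effect +
        stats::rnorm(config$n_mirnas, 0, config$noise_sd)
      data.frame(
        screen_id = screen_id, replicate = replicate, mirna_id = ids,
        firefly = 1000 * 2^log_ratio, renilla = 1000,
        stringsAsFactors = FALSE
      )
    }

    focal_effect <- ifelse(ids %in% targeting, config$effect_log2, 0)
    focal <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
      make_rows("MYCN", r, focal_effect)
    }))
    analog <- do.call(rbind, lapply(seq_len(config$n_analog_screens), function(k) {
      make_rows(sprintf("ANALOG%02d", k), 1L, 0)
    }))
    list(
      plates = rbind(focal, analog),
      truth = data.frame(mirna_id = ids, targeting = ids %in% targeting,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Configuration for the synthetic tumor cohort
#'
#' @param n_samples Number of tumor samples (default 160, a MYCN non-amplified
#'   cohort).
#' @param n_mirnas Number of profiled miRNAs (default 470).
#' @param n_genes Number of profiled mRNAs excluding MYCN (default 500).
#' @param planted_inverse Character vector of miRNA ids given a negative
#'   coupling to MYCN expression and activity.
#' @param planted_positive Character vector of miRNA ids given a positive
#'   coupling (empty by default).
#' @param coupling_r Target correlation magnitude in `[0, 1]` (default 0.6).
#' @param activity_gene_fraction Fraction of genes positively driven by the
#'   latent MYCN activity variable (default 0.1). Keep this small: the
#'   normalized enrichment score of even a perfectly bottom-ranked set is
#'   bounded by the reciprocal of the mean null ES magnitude, which grows
#'   with the set-to-universe ratio.
#' @param repressed_gene_fraction Fraction of genes negatively driven by the
#'   latent activity (default: same as `activity_gene_fraction`). MYC-family
#'   factors both activate and silence transcription; the repressed arm also
#'   keeps the gene-permutation GSEA null realistic by placing extreme
#'   ranking statistics at both ends of the list.
#' @param noise_sd Noise standard deviation on MYCN expression and on the
#'   activity-driven/repressed genes (default 1.5). At markedly lower values
#'   the co-regulated genes become so coherent that gene-permutation GSEA is
#'   no longer calibrated for null miRNAs; 1.5 keeps in-set ranking
#'   statistics close to exchangeable with the background while leaving the
#'   planted activity signal clearly detectable.
#' @param decorrelate_null Project chance in-sample correlation with the
#'   latent activity and MYCN out of the non-planted miRNAs (default `TRUE`),
#'   so that the planted truth labels are exact for downstream calling. Set
#'   to `FALSE` to study calibration under ordinary sampling noise, where
#'   null miRNAs carry chance coupling just like real cohorts.
#' @param seed Integer seed.
#' @return A list of class `"cohort_sim_config"`.
#' @export
cohort_sim_config <- function(n_samples = 160, n_mirnas = 470, n_genes = 500,
                              planted_inverse = character(),
                              planted_positive = character(),
                              coupling_r = 0.6, activity_gene_fraction = 0.1,
                              repressed_gene_fraction = activity_gene_fraction,
                              noise_sd = 1.5, decorrelate_null = TRUE,
                              seed = 1) {
  n_samples <- check_count(n_samples, "n_samples", min = 4L)
  n_mirnas <- check_count(n_mirnas, "n_mirnas")
  n_genes <- check_count(n_genes, "n_genes")
  if (coupling_r < 0 || coupling_r > 1) stop("coupling_r must be in [0, 1]")
  if (activity_gene_fraction < 0 || activity_gene_fraction > 1) {
    stop("activity_gene_fraction must be in [0, 1]")
  }
  if (repressed_gene_fraction < 0 ||
      activity_gene_fraction + repressed_gene_fraction > 1) {
    stop("activity and repressed gene fractions must sum to at most 1")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  ids <- sprintf("miR-%03d", seq_len(n_mirnas))
  if (!all(planted_inverse %in% ids) || !all(planted_positive %in% ids)) {
    stop("planted miRNA ids must be among the simulated ids (miR-001 ...)")
  }
  if (length(intersect(planted_inverse, planted_positive)) > 0L) {
    stop("a miRNA cannot be planted both inverse and positive")
  }
  structure(
    list(n_samples = n_samples, n_mirnas = n_mirnas, n_genes = n_genes,
         planted_inverse = planted_inverse, planted_positive = planted_positive,
         coupling_r = coupling_r, activity_gene_fraction = activity_gene_fraction,
         repressed_gene_fraction = repressed_gene_fraction,
         noise_sd = noise_sd, decorrelate_null = decorrelate_null, seed = seed),
    class = "cohort_sim_config"
  )
}

#' Simulate a tumor cohort with planted miRNA-MYCN coupling
#'
#' One latent MYCN-activity scalar per sample drives MYCN mRNA and a fraction
#' of "activity" genes; planted-inverse miRNAs are anti-coupled to the
#' standardized MYCN expression at the configured correlation magnitude.
#'
#' @param config A [cohort_sim_config()].
#' @return A list with `mirna` (miRNA x sample matrix), `mrna` (gene x sample
#'   matrix including a `"MYCN"` row) and `truth` (list with
#'   `planted_inverse`, `planted_positive`, `activity_genes`, `activity`
#'   latent vector).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    samples <- sprintf("tumor%03d", seq_len(n))
    activity <- stats::rnorm(n)
    mycn <- activity + stats::rnorm(n, 0, config$noise_sd)
    mycn_std <- as.numeric(scale(mycn))

    mirna_ids <- sprintf("miR-%03d", seq_len(config$n_mirnas))
    r <- config$coupling_r
    # basis for removing chance in-sample coupling from null miRNAs
    proj <- qr(cbind(1, activity, mycn))
    mirna <- t(vapply(mirna_ids, function(id) {
      if (id %in% config$planted_inverse) {
        -r * mycn_std + sqrt(1 - r^2) * stats::rnorm(n)
      } else if (id %in% config$planted_positive) {
        r * mycn_std + sqrt(1 - r^2) * stats::rnorm(n)
      } else if (config$decorrelate_null) {
        qr.resid(proj, stats::rnorm(n))
      } else {
        stats::rnorm(n)
      }
    }, numeric(n)))
    colnames(mirna) <- samples

    gene_ids <- sprintf("gene%04d", seq_len(config$n_genes))
    n_act <- round(config$activity_gene_fraction * config$n_genes)
    n_rep <- round(config$repressed_gene_fraction * config$n_genes)
    activity_genes <- gene_ids[seq_len(n_act)]
    repressed_genes <- gene_ids[n_act + seq_len(n_rep)]
    mrna <- t(vapply(gene_ids, function(g) {
      if (g %in% activity_genes) {
        activity + stats::rnorm(n, 0, config$noise_sd)
      } else if (g %in% repressed_genes) {
        -activity + stats::rnorm(n, 0, config$noise_sd)
      } else {
        stats::rnorm(n)
      }
    }, numeric(n)))
    mrna <- rbind(MYCN = mycn, mrna)
    colnames(mrna) <- samples

    list(
      mirna = mirna,
      mrna = mrna,
      truth = list(
        planted_inverse = config$planted_inverse,
        planted_positive = config$planted_positive,
        activity_genes = activity_genes,
        repressed_genes = repressed_genes,
        activity = stats::setNames(activity, samples)
      )
    )
  })
}

#' Configuration for the synthetic murine Cq time course
#'
#' Defaults mirror the progression design: genotypes TG and WT sampled at
#' weeks 1, 2 and 6 with 4 animals per genotype per timepoint.
#'
#' @param timepoints Ordered numeric sampling times in weeks
#'   (default `c(1, 2, 6)`).
#' @param n_per_group Animals per genotype per timepoint (default 4).
#' @param planted_slopes Named list: miRNA id -> numeric `c(TG = , WT = )`
#'   expression slopes in log2 units per week.
#' @param mirna_ids Full assay panel; defaults to the names of
#'   `planted_slopes`. Panel members without planted slopes are flat.
#' @param cq_noise_sd Gaussian noise SD on Cq (default 0.25 cycles).
#' @param cq_baseline Baseline Cq at expression 0 (default 25 cycles).
#' @param seed Integer seed.
#' @return A list of class `"timecourse_sim_config"`.
#' @export
timecourse_sim_config <- function(timepoints = c(1, 2, 6), n_per_group = 4,
                                  planted_slopes = list(),
                                  mirna_ids = names(planted_slopes),
                                  cq_noise_sd = 0.25, cq_baseline = 25,
                                  seed = 1) {
  if (length(unique(timepoints)) < 2L) stop("need at least 2 distinct timepoints")
  n_per_group <- check_count(n_per_group, "n_per_group", min = 2L)
  if (cq_noise_sd < 0) stop("cq_noise_sd must be >= 0")
  if (length(mirna_ids) == 0L) stop("panel is empty: supply mirna_ids or planted_slopes")
  if (!all(names(planted_slopes) %in% mirna_ids)) {
    stop("planted_slopes names must be in mirna_ids")
  }
  structure(
    list(timepoints = sort(unique(timepoints)), n_per_group = n_per_group,
         planted_slopes = planted_slopes, mirna_ids = mirna_ids,
         cq_noise_sd = cq_noise_sd, cq_baseline = cq_baseline, seed = seed),
    class = "timecourse_sim_config"
  )
}

#' Simulate a murine qPCR Cq time course
#'
#' Expression in log2 units is `slope_genotype * time_weeks`; Cq readings are
#' `cq_baseline - expression + noise` (lower Cq = higher expression). The
#' truth table reports both the planted delta-slope and the effective
#' delta-slope after global-mean normalization, which is identified relative
#' to the panel-average trend (`delta - mean(panel deltas)`).
#'
#' @param config A [timecourse_sim_config()].
#' @return A list with `cq` (miRNA x sample Cq matrix), `annotations` (data
#'   frame `sample_id`, `genotype`, `time_weeks`) and `truth` (data frame
#'   `mirna_id`, `slope_tg`, `slope_wt`, `delta_slope`,
#'   `effective_delta_slope`).
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "timecourse_sim_config"))
  with_seed(config$seed, {
    ann <- expand.grid(
      replicate = seq_len(config$n_per_group),
      time_weeks = config$timepoints,
      genotype = c("TG", "WT"),
      stringsAsFactors = FALSE
    )
    ann$sample_id <- sprintf("%s_w%g_r%d", ann$genotype, ann$time_weeks,
                             ann$replicate)
    ids <- config$mirna_ids
    slopes <- t(vapply(ids, function(id) {
      s <- config$planted_slopes[[id]]
      if (is.null(s)) c(TG = 0, WT = 0) else c(TG = s[["TG"]], WT = s[["WT"]])
    }, numeric(2)))

    expr <- vapply(seq_len(nrow(ann)), function(j) {
      slopes[, ann$genotype[j]] * ann$time_weeks[j]
    }, numeric(length(ids)))
    expr <- matrix(expr, nrow = length(ids))
    noise <- matrix(stats::rnorm(length(expr), 0, config$cq_noise_sd),
                    nrow = nrow(expr))
    cq <- config$cq_baseline - expr + noise
    dimnames(cq) <- list(ids, ann$sample_id)

    delta <- slopes[, "TG"] - slopes[, "WT"]
    list(
      cq = cq,
      annotations = ann[, c("sample_id", "genotype", "time_weeks")],
      truth = data.frame(
        mirna_id = ids,
        slope_tg = unname(slopes[, "TG"]),
        slope_wt = unname(slopes[, "WT"]),
        delta_slope = unname(delta),
        effective_delta_slope = unname(delta - mean(delta)),
        stringsAsFactors = FALSE
      )
    )
  })
}
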
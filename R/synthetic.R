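# Synthetic cfDNA cohort generator. Emulates the statistical structure the
# MRD method assumes: nucleosomal fragment-length mixtures with
# tumour-derived fragments shifted shorter, tumour-fraction-dependent
# mixing, compartment-structured variant read support (germline in BCP +
# tissue, CHIP in BCP only, trackable in tissue/preoperative plasma), and
# recurrence labels coupled to postoperative ctDNA. Hidden truth labels are
# retained so every classifier can be scored against generator truth.

#' Nucleosomal fragment-length profiles
#'
#' Discrete truncated-normal mixtures over fragment length. The built-in
#' profiles reproduce the qualitative cfDNA picture: non-tumour fragments
#' peak at the mononucleosomal ~167 bp (plus a dinucleosomal ~334 bp
#' shoulder), while tumour-derived fragments are shifted shorter (~145 bp
#' mono, ~300 bp di).
#'
#' @param type `"nontumour"` or `"tumour"`, or `"custom"` with `components`.
#' @param components For `type = "custom"`: a tibble with columns `mode`
#'   (bp), `spread` (sd, bp; 0 gives a point mass) and `weight` (summing
#'   to 1).
#' @return A tibble of mixture components of class `fragment_profile`.
#' @export
fragment_profile <- function(type = c("nontumour", "tumour", "custom"),
                             components = NULL) {
  type <- match.arg(type)
  comp <- switch(type,
    nontumour = tibble::tibble(mode = c(167, 334), spread = c(10, 25),
                               weight = c(0.8, 0.2)),
    tumour = tibble::tibble(mode = c(145, 300), spread = c(12, 30),
                            weight = c(0.85, 0.15)),
    custom = tibble::as_tibble(components))
  if (any(comp$weight < 0) || abs(sum(comp$weight) - 1) > 1e-8) {
    abort("profile weights must be non-negative and sum to 1")
  }
  if (any(comp$mode <= 0) || any(comp$spread < 0)) {
    abort("profile modes must be positive and spreads non-negative")
  }
  structure(comp, class = c("fragment_profile", class(comp)))
}

#' Exact discrete density of a fragment-length profile
#'
#' @param profile A [fragment_profile()].
#' @param length_cap Support upper bound (bp).
#' @return Numeric vector of probabilities over lengths `1:length_cap`,
#'   summing to 1.
#' @export
profile_density <- function(profile, length_cap = 600) {
  support <- seq_len(length_cap)
  dens <- numeric(length_cap)
  for (i in seq_len(nrow(profile))) {
    if (profile$spread[i] == 0) {
      d <- numeric(length_cap)
      m <- as.integer(round(profile$mode[i]))
      if (m < 1 || m > length_cap) abort("point-mass mode outside support")
      d[m] <- 1
    } else {
      d <- stats::dnorm(support, profile$mode[i], profile$spread[i])
      d <- d / sum(d)
    }
    dens <- dens + profile$weight[i] * d
  }
  dens
}

#' Sample a fragment pool from a length profile
#'
#' @param profile A [fragment_profile()].
#' @param n Number of fragments.
#' @param length_cap Support upper bound (bp).
#' @param seed Optional seed.
#' @param sample_id,source Pool attributes.
#' @return A [fragment_pool()].
#' @export
sample_fragment_pool <- function(profile, n, length_cap = 600, seed = NULL,
                                 sample_id = "synthetic",
                                 source = "nonmalignant") {
  if (n < 1) abort("n must be >= 1")
  dens <- profile_density(profile, length_cap)
  counts <- with_seed_if(seed, as.vector(rmultinom(1L, n, dens)))
  fragment_pool(counts = tibble::tibble(length = seq_len(length_cap),
                                        count = counts),
                sample_id = sample_id, source = source)
}

#' Sample a patient plasma pool with a given tumour fraction
#'
#' Each fragment is tumour-derived with probability `tumour_fraction`
#' (length drawn from the tumour profile) and non-tumour otherwise. The
#' realised tumour-fragment count is retained as hidden truth in the
#' `n_tumour` attribute.
#'
#' @param tumour_fraction Probability a fragment is tumour-derived, in
#'   `[0, 1]`.
#' @param n Total fragments.
#' @param tumour_profile,nontumour_profile [fragment_profile()]s.
#' @param length_cap Support upper bound (bp).
#' @param seed Optional seed.
#' @param sample_id,source Pool attributes.
#' @return A [fragment_pool()] with attribute `n_tumour`.
#' @export
sample_patient_pool <- function(tumour_fraction, n,
                                tumour_profile = fragment_profile("tumour"),
                                nontumour_profile = fragment_profile("nontumour"),
                                length_cap = 600, seed = NULL,
                                sample_id = "patient",
                                source = "patient_postop") {
  if (tumour_fraction < 0 || tumour_fraction > 1) {
    abort("tumour_fraction must be in [0, 1]")
  }
  with_seed_if(seed, {
    n_t <- rbinom(1L, n, tumour_fraction)
    ct <- if (n_t > 0) {
      as.vector(rmultinom(1L, n_t, profile_density(tumour_profile, length_cap)))
    } else numeric(length_cap)
    cn <- if (n - n_t > 0) {
      as.vector(rmultinom(1L, n - n_t,
                          profile_density(nontumour_profile, length_cap)))
    } else numeric(length_cap)
    pool <- fragment_pool(counts = tibble::tibble(length = seq_len(length_cap),
                                                  count = ct + cn),
                          sample_id = sample_id, source = source)
    attr(pool, "n_tumour") <- n_t
    pool
  })
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the study cohort structure: 36 patients of whom 14
#' recur, 15 non-malignant controls, ~5000x mean postoperative depth, and
#' per-patient trackable/CHIP/germline variant counts in the observed
#' ranges. Recurrent patients carry postoperative tumour fractions of
#' 5-15% (a well-separated regime); non-recurrent patients carry 0 unless
#' `contamination_rate` is raised.
#'
#' @param n_patients,n_recurrent Cohort size and number of recurrences.
#' @param n_controls Number of non-malignant control samples.
#' @param control_pool_size,patient_pool_size Fragments per control pool
#'   and per patient plasma pool (histogram representation, so large values
#'   are cheap).
#' @param tumour_profile,nontumour_profile Length profiles.
#' @param preop_tf_range Uniform range of preoperative tumour fraction.
#' @param recurrent_postop_tf_range Uniform range of postoperative tumour
#'   fraction for recurrent patients.
#' @param nonrecurrent_postop_tf Postoperative tumour fraction for
#'   non-recurrent patients (default 0).
#' @param contamination_rate,contamination_tf Fraction of non-recurrent
#'   patients receiving a residual tumour fraction, and its value.
#' @param n_trackable_range,n_chip_range,n_germline_range,n_uninformative_range
#'   Per-patient variant count ranges (inclusive).
#' @param mean_depth Mean sequencing depth (Poisson) per compartment.
#' @param tissue_af,germline_af Allele fractions in tissue and for
#'   germline variants.
#' @param chip_af_range Uniform range of CHIP allele fraction (shared by
#'   BCP and plasma, as CHIP is blood-derived).
#' @param pipeline_min_reads Alt reads at which the upstream caller is
#'   assumed to report a variant.
#' @param followup_recurrent,followup_nonrecurrent Uniform follow-up
#'   ranges (months); recurrence events occur within follow-up.
#' @param length_cap Fragment-length support upper bound (bp).
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 36, n_recurrent = 14,
                          n_controls = 15,
                          control_pool_size = 2e5,
                          patient_pool_size = 3e5,
                          tumour_profile = fragment_profile("tumour"),
                          nontumour_profile = fragment_profile("nontumour"),
                          preop_tf_range = c(0.02, 0.10),
                          recurrent_postop_tf_range = c(0.05, 0.15),
                          nonrecurrent_postop_tf = 0,
                          contamination_rate = 0, contamination_tf = 0.005,
                          n_trackable_range = c(3, 15),
                          n_chip_range = c(2, 8),
                          n_germline_range = c(2, 6),
                          n_uninformative_range = c(0, 2),
                          mean_depth = 5000,
                          tissue_af = 0.25, germline_af = 0.5,
                          chip_af_range = c(0.02, 0.2),
                          pipeline_min_reads = 5,
                          followup_recurrent = c(6, 24),
                          followup_nonrecurrent = c(18, 36),
                          length_cap = 600) {
  cfg <- as.list(environment())
  if (n_recurrent > n_patients) abort("n_recurrent cannot exceed n_patients")
  probs <- c(preop_tf_range, recurrent_postop_tf_range,
             nonrecurrent_postop_tf, contamination_rate, contamination_tf,
             tissue_af, germline_af, chip_af_range)
  if (any(probs < 0 | probs > 1)) abort("fractions and rates must be in [0, 1]")
  if (any(c(n_trackable_range, n_chip_range, n_germline_range,
            n_uninformative_range) < 0)) {
    abort("variant count ranges must be non-negative")
  }
  structure(cfg, class = "cohort_config")
}

sample_count_range <- function(range) {
  if (range[1] == range[2]) as.integer(range[1])
  else sample(seq.int(range[1], range[2]), 1L)
}

variant_rows <- function(patient_id, chrom, pos, ref, alt, compartments,
                         afs, mean_depth, pipeline_min_reads) {
  depth <- rpois(length(compartments), mean_depth)
  alt_reads <- rbinom(length(compartments), depth, afs)
  tibble::tibble(patient_id = patient_id, compartment = compartments,
                 chrom = chrom, pos = pos, ref = ref, alt = alt,
                 alt_reads = alt_reads, depth = depth,
                 pipeline_called = alt_reads >= pipeline_min_reads)
}

#' Generate a synthetic MRD cohort
#'
#' Draws a full cohort under the configured conditions: per-patient pre-
#' and postoperative plasma fragment pools, per-compartment variant
#' observations, supporting-fragment lengths (tumour-profile lengths for
#' trackable variants, non-tumour for CHIP), control pools, and outcome
#' metadata with recurrence coupled to postoperative tumour fraction.
#'
#' @param config A [cohort_config()].
#' @param seed Optional seed; the cohort is fully reproducible given it.
#' @return An `mrd_cohort` list: `metadata`, `pools` (patient_id,
#'   timepoint, length, count), `variants`, `support`, `controls`
#'   (control_id, length, count), and hidden `truth` (`patients`,
#'   `variants` tibbles).
#' @export
sample_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed_if(seed, {
    cfg <- config
    ids <- sprintf("P%02d", seq_len(cfg$n_patients))
    recurrence <- sample(rep(c(TRUE, FALSE),
                             c(cfg$n_recurrent, cfg$n_patients - cfg$n_recurrent)))
    preop_tf <- runif(cfg$n_patients, cfg$preop_tf_range[1], cfg$preop_tf_range[2])
    postop_tf <- ifelse(
      recurrence,
      runif(cfg$n_patients, cfg$recurrent_postop_tf_range[1],
            cfg$recurrent_postop_tf_range[2]),
      cfg$nonrecurrent_postop_tf +
        (runif(cfg$n_patients) < cfg$contamination_rate) * cfg$contamination_tf)
    followup <- ifelse(recurrence,
                       runif(cfg$n_patients, cfg$followup_recurrent[1],
                             cfg$followup_recurrent[2]),
                       runif(cfg$n_patients, cfg$followup_nonrecurrent[1],
                             cfg$followup_nonrecurrent[2]))
    metadata <- tibble::tibble(
      patient_id = ids, recurrence = recurrence,
      followup_months = round(followup, 1),
      adjuvant_status = sample(c("none", "partial", "completed"),
                               cfg$n_patients, replace = TRUE,
                               prob = c(0.6, 0.2, 0.2)),
      group = "nsclc")

    pools <- purrr::map2(ids, seq_len(cfg$n_patients), function(id, i) {
      pre <- sample_patient_pool(preop_tf[i], cfg$patient_pool_size,
                                 cfg$tumour_profile, cfg$nontumour_profile,
                                 cfg$length_cap, sample_id = id,
                                 source = "patient_preop")
      post <- sample_patient_pool(postop_tf[i], cfg$patient_pool_size,
                                  cfg$tumour_profile, cfg$nontumour_profile,
                                  cfg$length_cap, sample_id = id,
                                  source = "patient_postop")
      dplyr::bind_rows(
        tibble::tibble(patient_id = id, timepoint = "preop",
                       length = pre$length, count = pre$count),
        tibble::tibble(patient_id = id, timepoint = "postop",
                       length = post$length, count = post$count))
    }) |> purrr::list_rbind()

    dens_t <- profile_density(cfg$tumour_profile, cfg$length_cap)
    dens_n <- profile_density(cfg$nontumour_profile, cfg$length_cap)
    draw_lengths <- function(n, dens) {
      if (n == 0) return(integer(0))
      rep.int(seq_len(cfg$length_cap), as.vector(rmultinom(1L, n, dens)))
    }

    pos_counter <- 0L
    per_patient <- purrr::map(seq_len(cfg$n_patients), function(i) {
      id <- ids[i]
      n_tr <- sample_count_range(cfg$n_trackable_range)
      n_ch <- sample_count_range(cfg$n_chip_range)
      n_ge <- sample_count_range(cfg$n_germline_range)
      n_un <- sample_count_range(cfg$n_uninformative_range)
      n_all <- n_tr + n_ch + n_ge + n_un
      pos <- pos_counter + seq_len(n_all) * 10L
      pos_counter <<- pos_counter + n_all * 10L
      origin <- rep(c("tumour", "blood", "germline", "artifact"),
                    c(n_tr, n_ch, n_ge, n_un))
      keys <- tibble::tibble(patient_id = id, chrom = "chr1", pos = pos,
                             ref = "A", alt = "T", origin = origin)
      obs <- purrr::pmap(keys, function(patient_id, chrom, pos, ref, alt,
                                        origin) {
        switch(origin,
          tumour = variant_rows(patient_id, chrom, pos, ref, alt,
                                c("tissue", "preop_plasma", "postop_plasma"),
                                c(cfg$tissue_af, preop_tf[i] / 2,
                                  postop_tf[i] / 2),
                                cfg$mean_depth, cfg$pipeline_min_reads),
          blood = {
            af <- runif(1, cfg$chip_af_range[1], cfg$chip_af_range[2])
            variant_rows(patient_id, chrom, pos, ref, alt,
                         c("bcp", "preop_plasma", "postop_plasma"),
                         rep(af, 3), cfg$mean_depth, cfg$pipeline_min_reads)
          },
          germline = variant_rows(patient_id, chrom, pos, ref, alt,
                                  c("bcp", "tissue", "preop_plasma",
                                    "postop_plasma"),
                                  rep(cfg$germline_af, 4), cfg$mean_depth,
                                  cfg$pipeline_min_reads),
          artifact = variant_rows(patient_id, chrom, pos, ref, alt,
                                  "postop_plasma", cfg$pipeline_min_reads /
                                    cfg$mean_depth * 2,
                                  cfg$mean_depth, cfg$pipeline_min_reads))
      }) |> purrr::list_rbind()

      support <- obs |>
        dplyr::inner_join(keys, by = c("patient_id", "chrom", "pos", "ref",
                                       "alt")) |>
        dplyr::filter(.data$origin %in% c("tumour", "blood"),
                      .data$compartment %in% c("preop_plasma",
                                               "postop_plasma"),
                      .data$alt_reads > 0)
      support <- purrr::pmap(
        support[, c("patient_id", "compartment", "chrom", "pos", "ref",
                    "alt", "alt_reads", "origin")],
        function(patient_id, compartment, chrom, pos, ref, alt, alt_reads,
                 origin) {
          tibble::tibble(patient_id = patient_id, compartment = compartment,
                         chrom = chrom, pos = pos, ref = ref, alt = alt,
                         fragment_length = draw_lengths(
                           alt_reads,
                           if (origin == "tumour") dens_t else dens_n))
        }) |> purrr::list_rbind()
      list(variants = obs, support = support, truth = keys)
    })

    controls <- purrr::map(seq_len(cfg$n_controls), function(j) {
      p <- sample_fragment_pool(cfg$nontumour_profile, cfg$control_pool_size,
                                cfg$length_cap,
                                sample_id = sprintf("C%02d", j))
      tibble::tibble(control_id = sprintf("C%02d", j),
                     length = p$length, count = p$count)
    }) |> purrr::list_rbind()

    new_mrd_cohort(
      metadata = metadata,
      pools = pools,
      variants = purrr::list_rbind(purrr::map(per_patient, "variants")),
      support = purrr::list_rbind(purrr::map(per_patient, "support")),
      controls = controls,
      truth = list(
        patients = tibble::tibble(patient_id = ids, preop_tf = preop_tf,
                                  postop_tf = postop_tf),
        variants = purrr::list_rbind(purrr::map(per_patient, "truth"))),
      config = cfg)
  })
}

new_mrd_cohort <- function(metadata, pools, variants, support, controls,
                           truth = NULL, config = NULL) {
  structure(list(metadata = metadata, pools = pools, variants = variants,
                 support = support, controls = controls, truth = truth,
                 config = config),
            class = "mrd_cohort")
}

#' Assemble an MRD cohort from its component tables
#'
#' @param metadata Cohort metadata (see [read_cohort_metadata()]).
#' @param pools Long tibble of patient pools: `patient_id`, `timepoint`
#'   (`"preop"`/`"postop"`), `length`, `count`.
#' @param variants Variant observation tibble.
#' @param support Supporting-fragment tibble.
#' @param controls Long tibble of control pools: `control_id`, `length`,
#'   `count`.
#' @param truth Optional generator truth (synthetic cohorts only).
#' @return An `mrd_cohort`.
#' @export
mrd_cohort <- function(metadata, pools, variants, support, controls,
                       truth = NULL) {
  new_mrd_cohort(tibble::as_tibble(metadata), tibble::as_tibble(pools),
                 validate_variant_table(tibble::as_tibble(variants)),
                 tibble::as_tibble(support), tibble::as_tibble(controls),
                 truth)
}

#' @export
print.mrd_cohort <- function(x, ...) {
  cat(sprintf("<mrd_cohort> %d patients (%d recurrent), %d controls, %d variant observations\n",
              nrow(x$metadata), sum(x$metadata$recurrence),
              dplyr::n_distinct(x$controls$control_id), nrow(x$variants)))
  invisible(x)
}

#' Extract a patient's fragment pool from a cohort
#'
#' @param cohort An `mrd_cohort`.
#' @param patient_id Patient identifier.
#' @param timepoint `"postop"` (default) or `"preop"`.
#' @return A [fragment_pool()].
#' @export
cohort_pool <- function(cohort, patient_id, timepoint = "postop") {
  rows <- cohort$pools[cohort$pools$patient_id == patient_id &
                         cohort$pools$timepoint == timepoint, ]
  if (nrow(rows) == 0) {
    abort(sprintf("no %s fragment pool for patient '%s'", timepoint,
                  patient_id))
  }
  fragment_pool(counts = rows[, c("length", "count")],
                sample_id = patient_id,
                source = if (timepoint == "postop") "patient_postop"
                         else "patient_preop")
}

#' Extract control pools from a cohort
#'
#' @param cohort An `mrd_cohort`.
#' @param merged Merge all controls into one pooled non-malignant pool.
#' @return A single [fragment_pool()] if `merged`, else a named list of
#'   pools.
#' @export
control_pools <- function(cohort, merged = FALSE) {
  if (merged) {
    return(fragment_pool(counts = cohort$controls[, c("length", "count")],
                         sample_id = "controls_pooled",
                         source = "nonmalignant"))
  }
  ids <- unique(cohort$controls$control_id)
  setNames(lapply(ids, function(id) {
    fragment_pool(counts = cohort$controls[cohort$controls$control_id == id,
                                           c("length", "count")],
                  sample_id = id, source = "nonmalignant")
  }), ids)
}
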
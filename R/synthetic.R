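# Default per-(label, group) mean densities, individuals/m2. The named
# groups use the calibration group means; Maybe values without a measured
# mean are the Yes/No midpoint. The residual "other" group absorbs the
# remaining overall density per label (floored at zero, since the named
# group means for Yes already exceed the overall Yes mean).
.DEFAULT_GROUP_MEANS <- rbind(
  Yes   = c(Alcyonacea = 1.47, Scleractinia = 3.59,  Porifera = 1.29,
            Pennatulacea = 0),
  Maybe = c(Alcyonacea = 0.88, Scleractinia = 2.035, Porifera = 1.48,
            Pennatulacea = 1.415),
  No    = c(Alcyonacea = 0.29, Scleractinia = 0.48,  Porifera = 0.58,
            Pennatulacea = 0.97))

.DEFAULT_FLAG_PROBS <- rbind(
  Yes   = c(reef_present = 0.12, chemo_present = 0.03,
            large_old_present = 0.08, functional_role_visible = 0.04,
            threatened_present = 0.02),
  Maybe = c(reef_present = 0.02, chemo_present = 0.005,
            large_old_present = 0.03, functional_role_visible = 0.01,
            threatened_present = 0.005),
  No    = c(reef_present = 0, chemo_present = 0, large_old_present = 0,
            functional_role_visible = 0, threatened_present = 0))

#' Configuration for the synthetic annotation generator
#'
#' The defaults emulate the structure of a multi-laboratory image
#' calibration exercise: 10 laboratories contributing 27 sites at about 50
#' images per site, image areas log-uniform on 0.25-50 m^2 with a small
#' sub-1 m^2 fraction (38/1273), depths uniform on 100-4176 m, and
#' per-taxon-group counts drawn from a negative binomial whose mean is the
#' per-label group density times the imaged area — so per-image densities
#' are strongly overdispersed (SD well above the mean), as observed in real
#' expert-labelled survey data.
#'
#' @param n_labs,n_sites,images_per_site sampling structure.
#' @param n_images optional total image count overriding
#'   \code{n_sites * images_per_site} (images are spread over sites evenly).
#' @param area_range imaged-area range, m^2 (log-uniform).
#' @param sub1_fraction fraction of images below 1 m^2.
#' @param depth_range depth range, m (uniform).
#' @param label_probs named probabilities over Yes/Maybe/No (sum to 1).
#' @param group_means matrix of mean densities (individuals/m^2), rows
#'   Yes/Maybe/No, one column per taxon group; column names are the
#'   representative taxon used for the count column.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed); scalar or one value per taxon group.
#' @param flag_probs matrix of evidence-flag probabilities, rows
#'   Yes/Maybe/No, columns the five flags.
#' @param site_effect_sd SD of an optional log-normal site-level density
#'   multiplier (0 = off, the default: within-site correlation is real but
#'   unquantified, so it is not simulated unless asked for).
#' @return a validated config list of class \code{vme_generator_config}.
#' @export
generatorConfig <- function(n_labs = 10, n_sites = 27, images_per_site = 50,
                            n_images = NULL,
                            area_range = c(0.25, 50),
                            sub1_fraction = 38 / 1273,
                            depth_range = c(100, 4176),
                            label_probs = c(Yes = 0.40, Maybe = 0.15,
                                            No = 0.45),
                            group_means = .DEFAULT_GROUP_MEANS,
                            dispersion = 0.2,
                            flag_probs = .DEFAULT_FLAG_PROBS,
                            site_effect_sd = 0) {
  cfg <- list(n_labs = n_labs, n_sites = n_sites,
              images_per_site = images_per_site, n_images = n_images,
              area_range = area_range, sub1_fraction = sub1_fraction,
              depth_range = depth_range, label_probs = label_probs,
              group_means = group_means, dispersion = dispersion,
              flag_probs = flag_probs, site_effect_sd = site_effect_sd)
  stopifnot(n_labs >= 1, n_sites >= 1, images_per_site >= 1,
            area_range[1] > 0, area_range[2] >= area_range[1],
            sub1_fraction >= 0, sub1_fraction <= 1,
            all(label_probs >= 0), abs(sum(label_probs) - 1) < 1e-8,
            all(rownames(group_means) == .LABELS),
            all(group_means >= 0), all(dispersion > 0),
            all(flag_probs >= 0 & flag_probs <= 1), site_effect_sd >= 0)
  class(cfg) <- "vme_generator_config"
  cfg
}

#' Generate a synthetic annotation dataset
#'
#' Draws a fully reproducible \linkS4class{VmeImageSet} from a
#' [generatorConfig()]. Counts for taxon group t in an image of area A with
#' label L follow NegBin(mean = group_means[L, t] * A, size = dispersion),
#' so the expected per-image density is the configured group mean
#' independent of image area, with variance well above the mean. Evidence
#' flags are Bernoulli draws with per-label probabilities. Richness is
#' emergent from which counts are non-zero, not simulated directly.
#'
#' @param config a \code{vme_generator_config}.
#' @param seed integer RNG seed; the same seed gives a byte-identical
#'   dataset.
#' @return a \linkS4class{VmeImageSet}.
#' @examples
#' x <- generateAnnotations(generatorConfig(n_sites = 2), seed = 1)
#' @export
generateAnnotations <- function(config = generatorConfig(), seed = 1) {
  stopifnot(inherits(config, "vme_generator_config"))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  n_sites <- config$n_sites
  n <- if (!is.null(config$n_images)) config$n_images
       else n_sites * config$images_per_site
  site_of <- rep_len(seq_len(n_sites), n)
  site_of <- sort(site_of)
  lab_of <- rep_len(seq_len(config$n_labs), n_sites)[site_of]

  # areas: log-uniform below / at-or-above 1 m2 in configured proportions
  lo <- config$area_range[1]; hi <- config$area_range[2]
  sub1 <- stats::runif(n) < config$sub1_fraction & lo < 1
  area <- numeric(n)
  if (any(sub1))
    area[sub1] <- exp(stats::runif(sum(sub1), log(lo), log(min(1, hi))))
  area[!sub1] <- exp(stats::runif(sum(!sub1), log(max(lo, min(1, hi))),
                                  log(hi)))
  depth <- stats::runif(n, config$depth_range[1], config$depth_range[2])
  hard <- stats::runif(n, 0, 100)
  label <- sample(names(config$label_probs), n, replace = TRUE,
                  prob = config$label_probs)

  groups <- colnames(config$group_means)
  disp <- rep_len(config$dispersion, length(groups))
  site_mult <- if (config$site_effect_sd > 0)
    exp(stats::rnorm(n_sites, -config$site_effect_sd^2 / 2,
                     config$site_effect_sd)) else rep(1, n_sites)
  counts <- sapply(seq_along(groups), function(j) {
    mu <- config$group_means[label, groups[j]] * area * site_mult[site_of]
    stats::rnbinom(n, size = disp[j], mu = mu)
  })
  counts <- matrix(as.numeric(counts), nrow = n,
                   dimnames = list(NULL, groups))

  flags <- sapply(colnames(config$flag_probs), function(f)
    stats::runif(n) < config$flag_probs[label, f])
  flags <- matrix(as.logical(flags), nrow = n,
                  dimnames = list(NULL, colnames(config$flag_probs)))

  meta <- data.frame(
    image_id = sprintf("img%05d", seq_len(n)),
    laboratory = sprintf("lab%02d", lab_of),
    site = sprintf("site%02d", site_of),
    region = NA_character_,
    depth_m = depth, area_m2 = area, pct_hard_substrate = hard,
    camera = "simulated", label = label,
    stringsAsFactors = FALSE)
  meta <- cbind(meta, as.data.frame(flags))
  cts <- t(counts)
  colnames(cts) <- meta$image_id
  VmeImageSet(cts, meta)
}

#' Canned synthetic fixtures
#'
#' \describe{
#'   \item{tiny}{12 hand-checkable images covering every flow-chart branch
#'     (deterministic, no random draws).}
#'   \item{study_like}{the full generator defaults at 1,273 images across
#'     27 sites, including the sub-1 m^2 fraction.}
#'   \item{null_labels}{300 images whose density distributions are
#'     identical across labels (for type-I error checks).}
#'   \item{separated}{40 images with non-overlapping Yes/No overall
#'     densities (for threshold-recovery checks).}}
#'
#' @param name fixture name.
#' @param seed RNG seed for the stochastic fixtures.
#' @return a \linkS4class{VmeImageSet}.
#' @export
makeFixture <- function(name = c("tiny", "study_like", "null_labels",
                                 "separated"), seed = 1) {
  name <- match.arg(name)
  switch(name,
    tiny = .tiny_fixture(),
    study_like = generateAnnotations(generatorConfig(n_images = 1273),
                                     seed = seed),
    null_labels = {
      gm <- .DEFAULT_GROUP_MEANS
      gm["Yes", ] <- gm["No", ]; gm["Maybe", ] <- gm["No", ]
      fp <- .DEFAULT_FLAG_PROBS; fp[] <- 0
      generateAnnotations(generatorConfig(
        n_images = 300, sub1_fraction = 0,
        label_probs = c(Yes = 1/3, Maybe = 1/3, No = 1/3),
        group_means = gm, flag_probs = fp), seed = seed)
    },
    separated = .separated_fixture())
}

.tiny_fixture <- function() {
  taxa <- c("Alcyonacea", "Scleractinia", "Porifera", "Pennatulacea")
  cts <- matrix(0, 4, 12, dimnames = list(taxa, sprintf("t%02d", 1:12)))
  flags <- matrix(FALSE, 12, 5,
                  dimnames = list(NULL, .FLAG_COLS))
  label <- rep(NA_character_, 12)
  # 1: no evidence at all
  # 2: reef flag only            3: chemosynthetic flag
  # 4: large/old flag            5: functional role flag
  # 6: threatened flag           7: rich image (4 taxa, S >= 3)
  # 8: dense monotypic Alcyonacea stand
  # 9: combined density over tau_D without any single trigger
  # 10: sparse indicator presence, no step fires
  # 11: labelled Yes, moderate counts; 12: labelled No, sub-1 m2 area
  flags[2, "reef_present"] <- TRUE
  flags[3, "chemo_present"] <- TRUE
  flags[4, "large_old_present"] <- TRUE
  flags[5, "functional_role_visible"] <- TRUE
  flags[6, "threatened_present"] <- TRUE
  cts[, 7] <- c(1, 1, 1, 1)
  cts["Alcyonacea", 8] <- 10          # area 2 -> 5.0 /m2 >= 0.88
  cts["Pennatulacea", 9] <- 5         # area 1 -> D = 5 >= 4.16; S = 1 and
                                      # no per-taxon threshold, so only the
                                      # combined step can fire
  cts[, 10] <- c(1, 0, 0, 0)          # area 4 -> d = 0.25, nothing fires
  cts[, 11] <- c(2, 3, 1, 0)
  cts["Porifera", 12] <- 1
  label[7] <- "Yes"; label[11] <- "Yes"; label[10] <- "No"; label[12] <- "No"
  area <- c(2, 2, 2, 2, 2, 2, 2, 2, 1, 4, 2, 0.5)
  meta <- data.frame(image_id = colnames(cts),
                     laboratory = "lab01", site = "siteA",
                     region = NA_character_,
                     depth_m = seq(200, 2400, length.out = 12),
                     area_m2 = area,
                     pct_hard_substrate = seq(0, 100, length.out = 12),
                     camera = "fixture", label = label,
                     stringsAsFactors = FALSE)
  meta <- cbind(meta, as.data.frame(flags))
  VmeImageSet(cts, meta)
}

.separated_fixture <- function() {
  n <- 40
  taxa <- c("Alcyonacea", "Scleractinia", "Porifera", "Pennatulacea")
  cts <- matrix(0, 4, n, dimnames = list(taxa, sprintf("s%02d", 1:n)))
  label <- rep(c("Yes", "No"), each = 20)
  # area 2 m2 everywhere; Yes overall densities 5..10, No densities 0..0.95
  cts["Pennatulacea", 1:20] <- round(seq(5, 10, length.out = 20) * 2)
  cts["Porifera", 21:40] <- round(seq(0, 0.95, length.out = 20) * 2)
  meta <- data.frame(image_id = colnames(cts), laboratory = "lab01",
                     site = "siteS", region = NA_character_,
                     depth_m = 500, area_m2 = 2,
                     pct_hard_substrate = 50, camera = "fixture",
                     label = label, stringsAsFactors = FALSE)
  VmeImageSet(cts, meta)
}
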
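#' Construct a threshold configuration
#'
#' @param tau_S richness threshold, positive integer number of distinct
#'   indicator taxa.
#' @param tau_d named numeric vector of per-taxon monotypic-stand density
#'   thresholds (individuals/m^2); names must resolve in the registry used
#'   for classification. Taxa without an entry simply cannot fire the
#'   monotypic step but still count toward richness and combined density.
#' @param tau_D combined indicator density threshold (individuals/m^2).
#' @param richness_metric \code{"count"} (default) or \code{"per_area"}.
#' @return a \linkS4class{ThresholdConfig}.
#' @export
thresholdConfig <- function(tau_S, tau_d = numeric(), tau_D,
                            richness_metric = "count") {
  new("ThresholdConfig", tau_S = as.numeric(tau_S),
      tau_d = unlist(tau_d), tau_D = as.numeric(tau_D),
      richness_metric = richness_metric)
}

#' Packaged default thresholds
#'
#' Midpoints of the calibration Yes/No group means: tau_S = 3 taxa,
#' per-taxon densities Alcyonacea 0.88, Scleractinia 2.035, Porifera 0.935,
#' combined 4.16 individuals/m^2. These are placeholders derived from one
#' calibration exercise, intended to be replaced by regional values.
#'
#' @return a \linkS4class{ThresholdConfig}.
#' @export
defaultThresholds <- function() {
  readThresholds(system.file("extdata", "default_thresholds.yaml",
                             package = "vmeassess", mustWork = TRUE))
}

#' Read a threshold configuration from YAML
#'
#' @param path YAML file with fields \code{tau_S}, \code{tau_d} (a mapping
#'   taxon -> density), \code{tau_D}, and optionally
#'   \code{richness_metric}. A missing required field is an error naming it.
#' @return a \linkS4class{ThresholdConfig}.
#' @export
readThresholds <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("tau_S", "tau_D"))
    if (is.null(cfg[[f]])) stop("thresholds file is missing field: ", f)
  thresholdConfig(tau_S = cfg$tau_S,
                  tau_d = if (!is.null(cfg$tau_d)) unlist(cfg$tau_d)
                          else numeric(),
                  tau_D = cfg$tau_D,
                  richness_metric = cfg$richness_metric %||% "count")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
setMethod("show", "ThresholdConfig", function(object) {
  cat(sprintf("ThresholdConfig: tau_S = %g taxa (%s), tau_D = %g /m2\n",
              object@tau_S, object@richness_metric, object@tau_D))
  if (length(object@tau_d))
    cat("  tau_d:", paste(sprintf("%s = %g", names(object@tau_d),
                                  object@tau_d), collapse = ", "), "\n")
})

# Step order and the FAO criteria each positive step invokes.
.FLOW_STEPS <- c("reef", "chemosynthetic", "large_old", "functional_role",
                 "threatened", "richness_threshold", "monotypic_density",
                 "combined_density")

.STEP_CRITERIA <- list(
  reef = .FAO_CRITERIA,
  chemosynthetic = c("uniqueness_rarity", "functional_significance",
                     "fragility", "life_history"),
  large_old = c("uniqueness_rarity", "functional_significance", "fragility"),
  functional_role = "functional_significance",
  threatened = c("uniqueness_rarity", "functional_significance"),
  richness_threshold = "structural_complexity",
  monotypic_density = "structural_complexity",
  combined_density = "structural_complexity")

.STEP_FLAGS <- c(reef = "reef_present", chemosynthetic = "chemo_present",
                 large_old = "large_old_present",
                 functional_role = "functional_role_visible",
                 threatened = "threatened_present")

#' Classify images with the single-image VME decision flow chart
#'
#' A deterministic, short-circuiting rule engine. Step 0 ("element
#' detection") asks whether there is any evidence at all: an indicator taxon
#' with a positive count, or any evidence flag set. Without evidence the
#' verdict is \code{NO_EVIDENCE_EVALUATE_MORE} — the image does not show a
#' VME and more images from the site should be evaluated. With evidence, the
#' steps run in fixed order and the first "Yes" wins, each attaching the FAO
#' criteria it invokes: (1) reef present; (2) chemosynthetic ecosystem taxa
#' present; (3) large/old individual present; (4) visible functional role
#' (nursery, spawning, egg attachment); (5) threatened taxon present; (6)
#' indicator richness at or above \code{tau_S}; (7) any monotypic stand at
#' or above its per-taxon density threshold; (8) combined indicator density
#' at or above \code{tau_D}. If no step fires the verdict is
#' \code{NOT_VME_THIS_IMAGE}, again with the guidance that more images
#' should be evaluated before concluding absence.
#'
#' @param x a \linkS4class{VmeImageSet}.
#' @param registry a \linkS4class{VmeRegistry}.
#' @param body body id, \code{"union"} or \code{"intersection"}.
#' @param policy \code{"qualified_counts"} or \code{"strict"}.
#' @param thresholds a \linkS4class{ThresholdConfig}.
#' @return a [S4Vectors::DataFrame] with one row per image: \code{decision},
#'   \code{step_fired}, \code{fao_criteria} (comma-joined), and the
#'   supporting values \code{richness}, \code{max_density},
#'   \code{max_density_taxon}, \code{overall_density}, \code{guidance}.
#' @examples
#' res <- classifyImages(makeFixture("tiny"))
#' table(res$decision)
#' @export
classifyImages <- function(x, registry = defaultRegistry(),
                           body = "union",
                           policy = c("qualified_counts", "strict"),
                           thresholds = defaultThresholds()) {
  stopifnot(is(x, "VmeImageSet"), is(thresholds, "ThresholdConfig"))
  policy <- match.arg(policy)
  validObject(thresholds)
  if (ncol(x) == 0)
    return(S4Vectors::DataFrame(
      image_id = character(), decision = character(),
      step_fired = character(), fao_criteria = character(),
      richness = integer(), max_density = numeric(),
      max_density_taxon = character(), overall_density = numeric(),
      guidance = character()))
  dset <- computeDensities(x, registry, body = body, policy = policy)
  dens <- assay(dset, "density")
  cd <- colData(x)

  # per-taxon thresholds: resolve names once; unresolvable names are an error
  tau_d <- thresholds@tau_d
  if (length(tau_d)) {
    can <- resolveTaxon(registry, names(tau_d))
    if (anyNA(can))
      stop("tau_d taxa unresolvable in registry: ",
           paste(names(tau_d)[is.na(can)], collapse = ", "))
    tau_d <- tapply(tau_d, can, min)  # pool duplicates conservatively
  }

  n <- ncol(x)
  S <- colData(dset)$richness
  S_metric <- if (thresholds@richness_metric == "per_area")
    colData(dset)$richness_density else S
  D <- colData(dset)$overall_density

  thr_taxa <- intersect(names(tau_d), rownames(dens))
  if (length(thr_taxa)) {
    sub <- dens[thr_taxa, , drop = FALSE]
    ratio <- sweep(sub, 1, tau_d[thr_taxa], "/")
    hit_mono <- apply(ratio, 2, max) >= 1
    mono_taxon <- thr_taxa[apply(ratio, 2, which.max)]
  } else {
    hit_mono <- rep(FALSE, n)
    mono_taxon <- rep(NA_character_, n)
  }
  max_density <- if (nrow(dens)) apply(dens, 2, max) else rep(0, n)
  max_density_taxon <- if (nrow(dens))
    rownames(dens)[apply(dens, 2, which.max)] else rep(NA_character_, n)

  any_flag <- Reduce(`|`, lapply(.FLAG_COLS, function(f) cd[[f]]))
  any_count <- D > 0 | colSums(assay(x, "counts")) > 0
  has_evidence <- any_flag | any_count

  decision <- rep("NOT_VME_THIS_IMAGE", n)
  step <- rep("none", n)
  open <- has_evidence  # images still undecided
  decision[!open] <- "NO_EVIDENCE_EVALUATE_MORE"
  step[!open] <- "indicator_check"

  fire <- function(open, hit, name) {
    now <- open & hit
    decision[now] <<- "VME"
    step[now] <<- name
    open & !hit
  }
  for (s in names(.STEP_FLAGS))
    open <- fire(open, cd[[.STEP_FLAGS[s]]], s)
  open <- fire(open, S_metric >= thresholds@tau_S, "richness_threshold")
  open <- fire(open, hit_mono, "monotypic_density")
  open <- fire(open, D >= thresholds@tau_D, "combined_density")

  crit <- vapply(step, function(s)
    if (s %in% names(.STEP_CRITERIA))
      paste(.STEP_CRITERIA[[s]], collapse = ",") else "", character(1))
  guidance <- ifelse(decision == "VME", "",
    "more images from the site should be evaluated")
  S4Vectors::DataFrame(
    image_id = colnames(x), decision = decision, step_fired = step,
    fao_criteria = unname(crit), richness = S,
    max_density = as.numeric(max_density),
    max_density_taxon = max_density_taxon,
    overall_density = as.numeric(D), guidance = guidance,
    row.names = colnames(x))
}

#' @describeIn classifyImages classify a single image (a one-column
#'   \code{VmeImageSet} or a column index/id into \code{x}); returns a
#'   one-row \code{DataFrame}.
#' @param image column index or image id.
#' @export
classifyImage <- function(x, image = 1L, registry = defaultRegistry(),
                          body = "union",
                          policy = c("qualified_counts", "strict"),
                          thresholds = defaultThresholds()) {
  classifyImages(x[, image, drop = FALSE], registry = registry, body = body,
                 policy = policy, thresholds = thresholds)
}

#' Summarise flow-chart results
#'
#' @param results the \code{DataFrame} from [classifyImages()].
#' @return list with \code{by_decision} and \code{by_step} count tables;
#'   counts sum to the number of images.
#' @export
decisionSummary <- function(results) {
  list(by_decision = table(factor(results$decision,
         levels = c("VME", "NOT_VME_THIS_IMAGE",
                    "NO_EVIDENCE_EVALUATE_MORE"))),
       by_step = table(factor(results$step_fired,
         levels = c(.FLOW_STEPS, "indicator_check", "none"))))
}
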
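#' Load a VME indicator registry from file
#'
#' Reads a wide-format registry CSV (one row per taxon or feature, one column
#' per management body) together with an optional two-column synonym table
#' (\code{alias,canonical}). Status cells use the tokens \code{yes},
#' \code{no}, or \code{qualified:<note>}; \code{qualified!:<note>} marks a
#' cell whose source wording is ambiguous and stored verbatim. Called with no
#' arguments it loads the packaged default registry.
#'
#' @param path registry CSV; \code{NULL} for the packaged default.
#' @param synonyms_path synonyms CSV; \code{NULL} for the packaged default
#'   when \code{path} is \code{NULL}, otherwise no synonyms.
#' @param required_bodies optional character vector of body columns that must
#'   be present (a missing one is an error).
#' @return a \linkS4class{VmeRegistry}.
#' @examples
#' reg <- loadRegistry()
#' registryBodies(reg)
#' @export
loadRegistry <- function(path = NULL, synonyms_path = NULL,
                         required_bodies = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vme_registry.csv", package = "vmeassess",
                        mustWork = TRUE)
    if (is.null(synonyms_path))
      synonyms_path <- system.file("extdata", "vme_synonyms.csv",
                                   package = "vmeassess", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("registry file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- c("taxon", "rank", "group", "parent")
  miss <- setdiff(fixed, names(raw))
  if (length(miss))
    stop("registry is missing column(s): ", paste(miss, collapse = ", "))
  bodies <- setdiff(names(raw), fixed)
  if (!length(bodies)) stop("registry has no management-body columns")
  miss_b <- setdiff(required_bodies, bodies)
  if (length(miss_b))
    stop("missing body column(s): ", paste(miss_b, collapse = ", "))
  if (anyDuplicated(raw$taxon))
    stop("duplicate taxon row: ", raw$taxon[duplicated(raw$taxon)][1])

  parse_cell <- function(tok, taxon, body) {
    tok <- trimws(tok)
    low <- tolower(tok)
    if (low == "yes")
      return(list(status = "indicator", qualifier = NA_character_,
                  flagged = FALSE))
    if (low == "no")
      return(list(status = "not_indicator", qualifier = NA_character_,
                  flagged = FALSE))
    m <- regmatches(tok, regexec("^qualified(!?):(.+)$", tok))[[1]]
    if (length(m) == 3 && nzchar(trimws(m[3])))
      return(list(status = "qualified", qualifier = trimws(m[3]),
                  flagged = m[2] == "!"))
    stop(sprintf("unrecognized status token '%s' (taxon '%s', body '%s')",
                 tok, taxon, body))
  }

  status <- do.call(rbind, lapply(seq_len(nrow(raw)), function(i) {
    do.call(rbind, lapply(bodies, function(b) {
      cell <- parse_cell(raw[[b]][i], raw$taxon[i], b)
      data.frame(taxon = raw$taxon[i], body = b, status = cell$status,
                 qualifier = cell$qualifier, flagged = cell$flagged,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(status) <- NULL

  syn <- character()
  if (!is.null(synonyms_path)) {
    st <- utils::read.csv(synonyms_path, stringsAsFactors = FALSE)
    if (!all(c("alias", "canonical") %in% names(st)))
      stop("synonyms file must have columns alias, canonical")
    syn <- stats::setNames(trimws(st$canonical),
                           tolower(trimws(st$alias)))
  }

  entries <- raw[fixed]
  entries$parent[!nzchar(trimws(entries$parent))] <- NA_character_
  new("VmeRegistry", entries = entries, status = status,
      bodies = bodies, synonyms = syn)
}

.registry_cache <- new.env(parent = emptyenv())

#' Packaged default VME indicator registry
#'
#' The shipped registry covering eight management bodies (NPFC, SPRFMO,
#' NEAFC, NAFO_ABNJ, CCAMLR, SEAFO, GFCM, SIOFA) and 22 indicator taxa plus
#' two habitat features. Pre-revision octocoral taxonomy (Alcyonacea as an
#' order) is retained, matching current management lists; the synonym table
#' is the extension point for newer names.
#'
#' @return a \linkS4class{VmeRegistry} (cached after first load).
#' @export
defaultRegistry <- function() {
  if (is.null(.registry_cache$default))
    .registry_cache$default <- loadRegistry()
  .registry_cache$default
}

#' @describeIn VmeRegistry management-body identifiers in the registry
#' @param x,object a \code{VmeRegistry}
#' @export
registryBodies <- function(x) x@bodies

#' @describeIn VmeRegistry registry taxon/feature names
#' @export
registryTaxa <- function(x) x@entries$taxon

.norm_label <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Resolve free-text annotation labels to canonical registry taxa
#'
#' Resolution is case-insensitive and whitespace-stripping, applies the
#' synonym table (e.g. \code{Gorgonacea -> Alcyonacea}), and finally walks
#' upward through restricted-subtaxon qualifiers (e.g. \code{Goniocorella ->
#' Scleractinia}). Unknown labels resolve to \code{NA}, not an error, and
#' resolution is idempotent.
#'
#' @param registry a \linkS4class{VmeRegistry}.
#' @param labels character vector of annotation labels.
#' @return character vector of canonical taxon names, \code{NA} for unknown.
#' @examples
#' resolveTaxon(defaultRegistry(), c("Gorgonacea", "  PORIFERA ", "Widgetozoa"))
#' @export
resolveTaxon <- function(registry, labels) {
  stopifnot(is(registry, "VmeRegistry"))
  taxa <- registry@entries$taxon
  key <- .norm_label(labels)
  # synonym table first (closed under repeated application)
  for (i in 1:5) {
    hit <- key %in% names(registry@synonyms)
    if (!any(hit)) break
    key[hit] <- .norm_label(registry@synonyms[key[hit]])
  }
  out <- taxa[match(key, .norm_label(taxa))]
  # hierarchy walk: match restricted-subtaxon tokens in qualifiers
  todo <- which(is.na(out) & !is.na(labels) & nzchar(key))
  if (length(todo)) {
    qual <- registry@status[registry@status$status == "qualified", ]
    toks <- lapply(strsplit(qual$qualifier, "[;&]"), trimws)
    tok_taxon <- rep(qual$taxon, lengths(toks))
    toks <- unlist(toks)
    last_word <- sub("^.*\\s", "", toks)
    tok_key <- c(.norm_label(toks), .norm_label(last_word))
    tok_taxon <- c(tok_taxon, tok_taxon)
    out[todo] <- tok_taxon[match(key[todo], tok_key)]
  }
  out
}

.status_lookup <- function(registry, taxon, body) {
  s <- registry@status
  s[s$taxon == taxon & s$body == body, , drop = FALSE]
}

#' Indicator status of a taxon for one management body
#'
#' @param registry a \linkS4class{VmeRegistry}.
#' @param taxon taxon name (resolved through [resolveTaxon()]).
#' @param body a management-body identifier.
#' @return a list with \code{status} (\code{indicator}, \code{not_indicator}
#'   or \code{qualified}), \code{qualifier} and \code{flagged}; \code{NULL}
#'   if the taxon is unknown.
#' @export
indicatorStatus <- function(registry, taxon, body) {
  if (!body %in% registry@bodies)
    stop("unknown management body: ", body)
  can <- resolveTaxon(registry, taxon)
  if (is.na(can)) return(NULL)
  row <- .status_lookup(registry, can, body)
  list(taxon = can, status = row$status, qualifier = row$qualifier,
       flagged = row$flagged)
}

#' Is a taxon a VME indicator for a management body?
#'
#' Under the \code{strict} policy only plain listings count; under
#' \code{qualified_counts} (the default, since qualified entries list taxa
#' with members that are indicators) both plain and qualified listings count.
#'
#' @param registry a \linkS4class{VmeRegistry}.
#' @param taxon taxon name or free-text annotation label (vectorised).
#' @param body a management-body identifier.
#' @param policy \code{"qualified_counts"} or \code{"strict"}.
#' @return logical vector; \code{NA} for taxa the registry cannot resolve
#'   (unknown is distinct from "not an indicator").
#' @examples
#' reg <- defaultRegistry()
#' isIndicator(reg, "Scleractinia", "SPRFMO", policy = "strict")       # FALSE
#' isIndicator(reg, "Scleractinia", "SPRFMO")                          # TRUE
#' @export
isIndicator <- function(registry, taxon, body,
                        policy = c("qualified_counts", "strict")) {
  policy <- match.arg(policy)
  if (!body %in% registry@bodies)
    stop("unknown management body: ", body)
  can <- resolveTaxon(registry, taxon)
  s <- registry@status[registry@status$body == body, ]
  st <- s$status[match(can, s$taxon)]
  ok <- if (policy == "strict") st == "indicator"
        else st %in% c("indicator", "qualified")
  ok[is.na(can)] <- NA
  ok
}

.indicator_set <- function(registry, body, policy) {
  s <- registry@status[registry@status$body == body, ]
  keep <- if (policy == "strict") s$status == "indicator"
          else s$status %in% c("indicator", "qualified")
  s$taxon[keep]
}

#' Cross-region consensus lists of VME indicator taxa
#'
#' Combines the per-body indicator lists: \code{union} (an indicator
#' anywhere), \code{intersection} (an indicator everywhere), or
#' \code{at_least_k} (an indicator for at least \code{k} bodies). With the
#' default \code{qualified_counts} policy the full intersection of the
#' packaged registry is the three cnidarian orders Alcyonacea, Scleractinia
#' and Antipatharia.
#'
#' @param registry a \linkS4class{VmeRegistry}.
#' @param mode \code{"intersection"}, \code{"union"} or \code{"at_least_k"}.
#' @param k required number of bodies when \code{mode = "at_least_k"}.
#' @param policy \code{"qualified_counts"} or \code{"strict"}.
#' @return sorted character vector of taxon names.
#' @examples
#' consensusList(defaultRegistry(), "intersection")
#' @export
consensusList <- function(registry,
                          mode = c("intersection", "union", "at_least_k"),
                          k = NULL,
                          policy = c("qualified_counts", "strict")) {
  mode <- match.arg(mode)
  policy <- match.arg(policy)
  sets <- lapply(registry@bodies, .indicator_set,
                 registry = registry, policy = policy)
  if (mode == "at_least_k") {
    if (is.null(k) || k < 1 || k > length(registry@bodies))
      stop("k must lie in [1, number of bodies]")
    tab <- table(unlist(sets))
    return(sort(names(tab)[tab >= k]))
  }
  out <- Reduce(if (mode == "union") union else intersect, sets)
  sort(out)
}

#' Indicator taxa usable for density computations
#'
#' The set of registry taxa counted as indicators under a body or a
#' consensus rule, excluding habitat-feature rows (which are not countable
#' organisms) unless requested.
#'
#' @param registry a \linkS4class{VmeRegistry}.
#' @param body a body identifier, \code{"union"} or \code{"intersection"}.
#' @param policy \code{"qualified_counts"} or \code{"strict"}.
#' @param includeFeatures keep group = Feature rows?
#' @return character vector of taxon names.
#' @export
indicatorTaxa <- function(registry, body = "union",
                          policy = c("qualified_counts", "strict"),
                          includeFeatures = FALSE) {
  policy <- match.arg(policy)
  taxa <- if (body %in% c("union", "intersection"))
    consensusList(registry, mode = body, policy = policy)
  else if (body %in% registry@bodies)
    .indicator_set(registry, body, policy)
  else stop("unknown body or consensus mode: ", body)
  if (!includeFeatures) {
    feat <- registry@entries$taxon[registry@entries$group == "Feature"]
    taxa <- setdiff(taxa, feat)
  }
  sort(taxa)
}

#' @export
setMethod("show", "VmeRegistry", function(object) {
  cat("VmeRegistry:", nrow(object@entries), "taxa/features x",
      length(object@bodies), "bodies\n")
  cat("  bodies:", paste(object@bodies, collapse = ", "), "\n")
  n_q <- sum(object@status$status == "qualified")
  cat("  qualified cells:", n_q,
      " synonyms:", length(object@synonyms), "\n")
})
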
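#' Construct an ethogram
#'
#' An ethogram is the catalogue of mutually exclusive behaviors used to score
#' observations.  Each behavior carries a functional class (static, active,
#' eat, comfort, interaction or other) and a flag marking behaviors that are
#' left out of occurrence-category binning (typically a catch-all "Others"
#' bucket).
#'
#' @param behaviors Character vector of unique, non-empty behavior names.
#' @param class Functional class per behavior; recycled if length 1.
#'   One of `"static"`, `"active"`, `"eat"`, `"comfort"`, `"interaction"`,
#'   `"other"`.
#' @param ontology_id Optional ontology accession per behavior (e.g. ATOL
#'   ids); `NA` where unknown.
#' @param excluded_from_binning Logical per behavior; excluded behaviors are
#'   skipped when assigning occurrence categories but still contribute to
#'   occurrence values.
#'
#' @return A tibble of class `"ethogram"` with columns `behavior`, `class`,
#'   `ontology_id`, `excluded_from_binning`.
#' @seealso [load_ethogram()], [broiler_ethogram()]
#' @examples
#' ethogram(c("Walking", "Resting"), class = c("active", "static"))
#' @export
ethogram <- function(behaviors,
                     class = "other",
                     ontology_id = NA_character_,
                     excluded_from_binning = FALSE) {
  if (length(behaviors) < 1) stop_scanopt("an ethogram needs at least one behavior")
  behaviors <- as.character(behaviors)
  if (anyNA(behaviors) || any(!nzchar(behaviors))) {
    stop_scanopt("behavior names must be non-empty")
  }
  if (anyDuplicated(behaviors)) {
    dup <- unique(behaviors[duplicated(behaviors)])
    stop_scanopt("duplicate behavior name(s): ", paste(dup, collapse = ", "))
  }
  classes <- c("static", "active", "eat", "comfort", "interaction", "other")
  class <- rep_len(as.character(class), length(behaviors))
  bad <- setdiff(unique(class), classes)
  if (length(bad)) {
    stop_scanopt("unknown behavior class(es): ", paste(bad, collapse = ", "))
  }
  out <- tibble::tibble(
    behavior = behaviors,
    class = class,
    ontology_id = rep_len(as.character(ontology_id), length(behaviors)),
    excluded_from_binning = rep_len(as.logical(excluded_from_binning),
                                    length(behaviors))
  )
  class(out) <- c("ethogram", class(out))
  out
}

#' Read an ethogram definition file
#'
#' Reads a JSON or YAML file whose top level is either a list of behavior
#' entries or a mapping with a `behaviors` key.  Each entry has a `name`
#' (required) plus optional `class`, `ontology_id`, `excluded_from_binning`
#' and `aliases` fields.  Aliases let files written with synonymous behavior
#' names (e.g. "Preening" for "Self-grooming") resolve to one canonical
#' name via [resolve_behavior_names()].
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An [ethogram()] with an `aliases` attribute (named character
#'   vector mapping alias to canonical name, possibly empty).
#' @examples
#' path <- system.file("extdata", "ethogram_broiler.json", package = "scanopt")
#' eth <- load_ethogram(path)
#' nrow(eth)
#' @export
load_ethogram <- function(path) {
  if (!file.exists(path)) stop_scanopt("ethogram file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  entries <- raw[["behaviors"]] %||% raw
  if (length(entries) == 0) stop_scanopt("ethogram file defines no behaviors")
  get_field <- function(e, field, default) e[[field]] %||% default
  names_ <- vapply(entries, function(e) {
    nm <- get_field(e, "name", NULL)
    if (is.null(nm)) stop_scanopt("every ethogram entry needs a `name`")
    as.character(nm)
  }, character(1))
  eth <- ethogram(
    behaviors = names_,
    class = vapply(entries, get_field, character(1),
                   field = "class", default = "other"),
    ontology_id = vapply(entries, function(e) {
      as.character(get_field(e, "ontology_id", NA_character_))
    }, character(1)),
    excluded_from_binning = vapply(entries, function(e) {
      isTRUE(get_field(e, "excluded_from_binning", FALSE))
    }, logical(1))
  )
  alias_list <- lapply(entries, function(e) unlist(e[["aliases"]]))
  aliases <- setNames(
    rep(names_, lengths(alias_list)),
    unlist(alias_list) %||% character(0)
  )
  if (any(names(aliases) %in% names_)) {
    stop_scanopt("alias collides with a canonical behavior name")
  }
  attr(eth, "aliases") <- aliases
  eth
}

#' Resolve behavior-name synonyms against an ethogram
#'
#' Maps a vector of behavior names onto the ethogram's canonical names using
#' its alias table, erroring on names that are neither canonical nor aliased.
#'
#' @param x Character vector of behavior names.
#' @param eth An [ethogram()].
#' @return `x` with aliases replaced by canonical names.
#' @export
resolve_behavior_names <- function(x, eth) {
  aliases <- attr(eth, "aliases") %||% character(0)
  out <- x
  if (length(aliases)) {
    hit <- match(x, names(aliases))
    out[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  unknown <- setdiff(unique(out), eth$behavior)
  if (length(unknown)) {
    stop_scanopt("behavior(s) not in ethogram: ", paste(unknown, collapse = ", "))
  }
  out
}

#' Packaged pasture-broiler ethogram
#'
#' The 20-entry ethogram used throughout the examples: 19 scored behaviors of
#' slow-growing broiler chickens on pasture (static, active, eating, comfort
#' and social-interaction classes, with ATOL ontology accessions) plus a
#' catch-all "Others" bucket that is excluded from occurrence-category
#' binning.  Synonyms common in the literature (Preening for Self-grooming,
#' Fluffing for Swelling, Allopreening for Allo-grooming) are carried as
#' aliases.
#'
#' @return An [ethogram()] with 20 behaviors.
#' @examples
#' broiler_ethogram()
#' @export
broiler_ethogram <- function() {
  load_ethogram(system.file("extdata", "ethogram_broiler.json",
                            package = "scanopt", mustWork = TRUE))
}
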
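#' Identification hierarchy of species codes and morphological groups
#'
#' Visible-migration counts record birds under short species codes when
#' identification succeeds, and under nested morphological-group codes
#' ("ringtail harrier", "large eagle", "unknown raptor", ...) when it does
#' not. The hierarchy object holds, for every code:
#' \itemize{
#'   \item \code{parent}: the immediately more general group (NA at a root),
#'   \item \code{pools}: for each group, the set of species-level codes whose
#'     identified counts define the allocation proportions for that group,
#'   \item \code{status}: monitoring status (\code{priority}, \code{secondary},
#'     \code{none}) per species,
#'   \item \code{age_codes}: the dedicated age-protocol codes (e.g.
#'     \code{HB_JUV}) mapped to their parent species. Age-protocol codes are
#'     sampling records and are never mixed into regular-count totals.
#' }
#'
#' @param overrides optional named list with any of \code{parent},
#'   \code{pools}, \code{status} entries to merge over the packaged default
#'   (e.g. a corrected group-membership reading).
#' @return an object of class \code{id_hierarchy}.
#' @export
#' @examples
#' h <- default_hierarchy()
#' ancestors("HB", h)
default_hierarchy <- function(overrides = NULL) {
  parent <- c(
    # buzzards / kites
    HB = "Pernis_SPEC", CrestedHB = "Pernis_SPEC",
    StepBuz = "Buzzard_SPEC", CommonBuz = "Buzzard_SPEC",
    RoughLB = "Buzzard_SPEC", LongLB = "Buzzard_SPEC",
    BlackKite = "MediumRaptor", RedKite = "MediumRaptor",
    # eagles
    LesserSE = "LargeEAGLE", GreaterSE = "LargeEAGLE", SteppeE = "LargeEAGLE",
    ImperialE = "LargeEAGLE", GoldenE = "LargeEAGLE", WhiteTE = "LargeEAGLE",
    BootedE = "Raptor_SPEC", ShortTE = "Raptor_SPEC", Osprey = "Raptor_SPEC",
    # vultures
    EgyptianV = "Raptor_SPEC", GriffonV = "Raptor_SPEC", BlackV = "Raptor_SPEC",
    # harriers
    Mar = "Harrier_SPEC", Mon = "MonPalHen", Pal = "MonPalHen",
    Hen = "MonPalHen",
    # sparrowhawks / goshawk
    LevantSH = "SparrowH_SPEC", EurasianSH = "SparrowH_SPEC",
    Goshawk = "SPH_Goshawk",
    # falcons
    LesserKes = "Kestrel_SPEC", CommonKes = "Kestrel_SPEC",
    RedFF = "Hobby_RedFF", Hobby = "Hobby_RedFF",
    EleonoraF = "Falcon_SPEC", Merlin = "Falcon_SPEC",
    LannerF = "LargeFALCON", SakerF = "LargeFALCON", Peregrine = "LargeFALCON",
    # non-raptors
    WhiStork = "Stork_SPEC", BlaStork = "Stork_SPEC",
    EurasianCrane = NA, DemCrane = NA, WhiteP = NA, DalmatianP = NA,
    Roller = NA, TurtleD = NA, WoodP = NA, StockD = NA,
    # group chain
    Pernis_SPEC = "Buzzard_SPEC", Buzzard_SPEC = "MediumRaptor",
    MediumRaptor = "Raptor_SPEC", LargeEAGLE = "Raptor_SPEC",
    MonPalHen = "Harrier_SPEC", Harrier_SPEC = "Raptor_SPEC",
    SparrowH_SPEC = "SPH_Goshawk", SPH_Goshawk = "Raptor_SPEC",
    Hobby_RedFF = "Falcon_SPEC", Kestrel_SPEC = "Falcon_SPEC",
    LargeFALCON = "Falcon_SPEC", Falcon_SPEC = "Raptor_SPEC",
    Raptor_SPEC = NA, Stork_SPEC = NA
  )

  buzzards <- c("HB", "CrestedHB", "StepBuz", "CommonBuz", "RoughLB", "LongLB")
  falcons <- c("LesserKes", "CommonKes", "RedFF", "EleonoraF", "Merlin",
               "Hobby", "LannerF", "SakerF", "Peregrine")
  eagles <- c("LesserSE", "GreaterSE", "SteppeE", "ImperialE", "GoldenE",
              "WhiteTE")
  harriers <- c("Mar", "Mon", "Pal", "Hen")
  accipiters <- c("LevantSH", "EurasianSH", "Goshawk")
  raptors <- c(buzzards, "BlackKite", "RedKite", eagles, "BootedE", "ShortTE",
               "Osprey", "EgyptianV", "GriffonV", "BlackV", harriers,
               accipiters, falcons)

  pools <- list(
    Pernis_SPEC   = c("HB", "CrestedHB"),
    Buzzard_SPEC  = buzzards,
    MediumRaptor  = c(buzzards, "BlackKite", "RedKite"),
    LargeEAGLE    = eagles,
    MonPalHen     = c("Mon", "Pal", "Hen"),
    Harrier_SPEC  = harriers,
    SparrowH_SPEC = c("LevantSH", "EurasianSH"),
    SPH_Goshawk   = accipiters,
    Hobby_RedFF   = c("Hobby", "RedFF"),
    Kestrel_SPEC  = c("LesserKes", "CommonKes"),
    LargeFALCON   = c("LannerF", "SakerF", "Peregrine"),
    Falcon_SPEC   = falcons,
    Raptor_SPEC   = raptors,
    Stork_SPEC    = c("WhiStork", "BlaStork")
  )

  status <- stats::setNames(rep("none", length(parent)), names(parent))
  status[c("HB", "BlackKite", "LesserSE", "BootedE", "Mar", "Mon", "Pal")] <-
    "priority"
  status[c("StepBuz", "GreaterSE", "SteppeE", "ImperialE", "ShortTE", "Osprey",
           "Hen", "EgyptianV", "GriffonV", "BlackV", "LannerF", "SakerF",
           "Peregrine", "WhiStork", "BlaStork", "EurasianCrane", "DemCrane",
           "WhiteP", "DalmatianP", "Roller", "TurtleD", "WoodP",
           "StockD")] <- "secondary"
  status[names(pools)] <- "none"

  age_codes <- c(
    HB_JUV = "HB", HB_NONJUV = "HB",
    BK_JUV = "BlackKite", BK_NONJUV = "BlackKite",
    SB_JUV = "StepBuz", SB_NONJUV = "StepBuz"
  )

  if (!is.null(overrides)) {
    if (!is.null(overrides$parent)) {
      parent[names(overrides$parent)] <- unlist(overrides$parent)
    }
    if (!is.null(overrides$pools)) {
      for (g in names(overrides$pools)) pools[[g]] <- overrides$pools[[g]]
    }
    if (!is.null(overrides$status)) {
      status[names(overrides$status)] <- unlist(overrides$status)
    }
  }

  h <- structure(
    list(
      parent = parent,
      pools = pools,
      status = status,
      age_codes = age_codes,
      groups = names(pools),
      species = setdiff(names(parent), names(pools))
    ),
    class = "id_hierarchy"
  )
  validate_hierarchy(h)
  h
}

#' Load an identification hierarchy from a YAML config file
#'
#' The file may contain `parent:`, `pools:` and `status:` maps; anything not
#' given falls back to the packaged default, so a corrected group-membership
#' reading can be dropped in without restating the whole taxonomy.
#'
#' @param path path to a YAML file.
#' @return an \code{id_hierarchy}.
#' @export
load_hierarchy <- function(path) {
  cfg <- yaml::read_yaml(path)
  default_hierarchy(overrides = cfg$taxonomy %||% cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_hierarchy <- function(h) {
  stopifnot(inherits(h, "id_hierarchy"))
  # acyclic and rooted: every code must terminate by walking parents
  for (code in names(h$parent)) {
    seen <- character()
    cur <- code
    while (!is.na(h$parent[[cur]])) {
      if (cur %in% seen) stop("cycle in hierarchy at ", cur)
      seen <- c(seen, cur)
      cur <- h$parent[[cur]]
      if (!cur %in% names(h$parent)) stop("unknown parent ", cur)
    }
  }
  # every raptor code reaches Raptor_SPEC
  for (s in h$pools$Raptor_SPEC) {
    if (!"Raptor_SPEC" %in% ancestors(s, h)) {
      stop(s, " does not reach Raptor_SPEC")
    }
  }
  for (g in names(h$pools)) {
    if (length(h$pools[[g]]) == 0) stop("empty pool for ", g)
    bad <- setdiff(h$pools[[g]], h$species)
    if (length(bad)) stop("pool of ", g, " has non-species codes: ",
                          paste(bad, collapse = ", "))
  }
  invisible(h)
}

#' Resolve a text code to a known species, group or age-protocol code
#'
#' Matching is case-sensitive on the protocol abbreviation set.
#'
#' @param text character vector of codes as they appear in a data file.
#' @param hierarchy an \code{id_hierarchy}.
#' @return the input codes, validated.
#' @export
resolve_code <- function(text, hierarchy) {
  known <- c(names(hierarchy$parent), names(hierarchy$age_codes))
  bad <- setdiff(unique(text), known)
  if (length(bad)) {
    stop("unknown species code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  text
}

#' Is a code a morphological group (as opposed to a species)?
#' @param code character vector of codes.
#' @param hierarchy an \code{id_hierarchy}.
#' @return logical vector.
#' @export
is_group <- function(code, hierarchy) code %in% hierarchy$groups

#' Map age-protocol codes to their parent species
#'
#' Regular codes pass through unchanged; \code{HB_JUV} becomes \code{HB}, etc.
#' @inheritParams is_group
#' @return character vector of species/group codes.
#' @export
base_code <- function(code, hierarchy) {
  idx <- match(code, names(hierarchy$age_codes))
  ifelse(is.na(idx), code, unname(hierarchy$age_codes[idx]))
}

#' Ancestor groups of a code, most specific first
#'
#' The code itself is excluded; a root returns an empty vector. Age-protocol
#' codes are resolved to their parent species first.
#'
#' @param code a single code.
#' @param hierarchy an \code{id_hierarchy}.
#' @return character vector of group codes from most specific to most general.
#' @export
#' @examples
#' ancestors("HB", default_hierarchy())
#' # "Pernis_SPEC" "Buzzard_SPEC" "MediumRaptor" "Raptor_SPEC"
ancestors <- function(code, hierarchy) {
  code <- base_code(code, hierarchy)
  if (!code %in% names(hierarchy$parent)) {
    stop("unknown code: ", code, call. = FALSE)
  }
  out <- character()
  cur <- hierarchy$parent[[code]]
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- hierarchy$parent[[cur]]
  }
  out
}

#' Could two codes refer to the same bird?
#'
#' True iff the codes are equal, or one is an ancestor group of the other.
#' Used when pairing records across stations: a "MonPalHen" record can be the
#' same birds as a "Pal" record, but not as a "Mon" vs "Pal" pair.
#'
#' @param a,b single codes.
#' @param hierarchy an \code{id_hierarchy}.
#' @return logical.
#' @export
taxon_compatible <- function(a, b, hierarchy) {
  a <- base_code(a, hierarchy)
  b <- base_code(b, hierarchy)
  a == b || a %in% ancestors(b, hierarchy) || b %in% ancestors(a, hierarchy)
}

#' The more general of two taxon-compatible codes
#' @inheritParams taxon_compatible
#' @return a single code.
#' @export
more_general <- function(a, b, hierarchy) {
  a <- base_code(a, hierarchy)
  b <- base_code(b, hierarchy)
  if (a == b) return(a)
  if (a %in% ancestors(b, hierarchy)) return(a)
  if (b %in% ancestors(a, hierarchy)) return(b)
  stop("codes ", a, " and ", b, " are not taxon-compatible", call. = FALSE)
}

# depth = number of ancestors; used to process groups bottom-up
hierarchy_depth <- function(code, hierarchy) {
  length(ancestors(code, hierarchy))
}
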
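#' Read a property-group table from YAML
#'
#' A property-group table assigns every amino acid to one of three groups
#' for each physicochemical property. The packaged default covers eight
#' properties (secondary structure, solvent accessibility, normalized Van
#' der Waals volume, hydrophobicity, charge, polarizability, polarity,
#' surface tension); users with a different division scheme can supply
#' their own file in the same layout (see
#' `system.file("extdata/property_groups.yaml", package = "cytosel")`).
#'
#' Property order and group order in the file are significant: feature
#' columns are indexed by them, so two tables with the same memberships but
#' different ordering produce differently ordered feature vectors.
#'
#' @param path Path to a YAML file with a top-level `properties` list;
#'   each entry has `name`, `code` and a named `groups` map of three
#'   residue strings.
#' @return A `property_group_table` object: an ordered list of properties,
#'   each with `name`, `code` and `groups` (a named list of three
#'   character vectors of residues).
#' @export
read_property_groups <- function(path) {
  if (!file.exists(path)) {
    stop("property-group file not found: '", path, "'", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$properties)) {
    stop("'", path, "' has no top-level 'properties' list", call. = FALSE)
  }
  props <- lapply(raw$properties, function(p) {
    groups <- lapply(p$groups, function(g) {
      strsplit(toupper(gsub("[[:space:]]", "", g)), "", fixed = TRUE)[[1]]
    })
    list(name = p$name, code = p$code, groups = groups)
  })
  table <- structure(props, class = "property_group_table")
  validate_property_groups(table)
  table
}

#' Validate a property-group table
#'
#' Checks that, for every property, the three groups are nonempty,
#' pairwise disjoint, and jointly cover the full 20-letter alphabet, and
#' that property names/codes are unique.
#'
#' @param table A `property_group_table`.
#' @return `table`, invisibly; errors describe the first violation found.
#' @export
validate_property_groups <- function(table) {
  if (length(table) == 0L) {
    stop("property-group table has no properties", call. = FALSE)
  }
  codes <- vapply(table, `[[`, "", "code")
  names <- vapply(table, `[[`, "", "name")
  if (anyDuplicated(codes) || anyDuplicated(names)) {
    stop("property names and codes must be unique", call. = FALSE)
  }
  for (p in table) {
    if (length(p$groups) != 3L) {
      stop("property '", p$name, "' must have exactly 3 groups",
        call. = FALSE
      )
    }
    if (any(lengths(p$groups) == 0L)) {
      stop("property '", p$name, "' has an empty group", call. = FALSE)
    }
    members <- unlist(p$groups, use.names = FALSE)
    if (anyDuplicated(members)) {
      stop(
        "property '", p$name, "': residue(s) in more than one group: ",
        paste(unique(members[duplicated(members)]), collapse = ", "),
        call. = FALSE
      )
    }
    if (!setequal(members, AA_ALPHABET)) {
      stop(
        "property '", p$name,
        "': groups do not partition the 20-letter alphabet",
        call. = FALSE
      )
    }
  }
  invisible(table)
}

# Cache for the packaged default table.
.pkg_env <- new.env(parent = emptyenv())

#' The default property-group table
#'
#' Loads (and caches) the packaged eight-property table. The secondary-
#' structure helix group is \{E,A,L,M,Q,K,R,H\}; the remaining memberships
#' follow the canonical three-group CTD divisions of the feature-extraction
#' literature.
#'
#' @return A `property_group_table` with 8 properties.
#' @export
default_property_groups <- function() {
  if (is.null(.pkg_env$default_groups)) {
    path <- system.file("extdata", "property_groups.yaml",
      package = "cytosel", mustWork = TRUE
    )
    .pkg_env$default_groups <- read_property_groups(path)
  }
  .pkg_env$default_groups
}

#' @export
print.property_group_table <- function(x, ...) {
  cat("Property-group table (", length(x), " properties)\n", sep = "")
  for (p in x) {
    cat("  ", p$name, " [", p$code, "]: ",
      paste(
        vapply(
          p$groups,
          function(g) paste(g, collapse = ""), ""
        ),
        collapse = " | "
      ),
      "\n",
      sep = ""
    )
  }
  invisible(x)
}

# Integer group membership (1/2/3) per alphabet position, one row per
# property. Used by all CTD feature computations.
group_index_matrix <- function(table) {
  m <- matrix(NA_integer_, nrow = length(table), ncol = 20L)
  for (i in seq_along(table)) {
    for (g in 1:3) {
      m[i, match(table[[i]]$groups[[g]], AA_ALPHABET)] <- g
    }
  }
  m
}
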
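#' Synthetic 360-parcel atlas with functional-network assignments
#'
#' Builds a deterministic stand-in for a 360-region cortical parcellation with
#' functional-network labels. The real published assignment table cannot be
#' redistributed, so this fixture reproduces only the network cardinalities
#' used in the subnetwork analyses: 56 Cingulo-opercular + 6 Orbito-affective
#' parcels (salience network, 62 nodes) and 23 Dorsal attention +
#' 50 Frontoparietal parcels (cognitive control network, 73 nodes); the
#' remaining 225 parcels are labelled \code{"Other"}. Region identifiers follow
#' an \code{L_###}/\code{R_###} hemisphere convention. A user-supplied real
#' assignment table in the same schema can be loaded with [load_atlas()].
#'
#' @return A data.frame with columns \code{region_id}, \code{hemisphere}
#'   (\code{"L"}/\code{"R"}) and \code{functional_network}, 360 rows.
#' @seealso [load_atlas()], [network_nodes()]
#' @export
#' @examples
#' atl <- synthetic_atlas()
#' table(atl$functional_network)
synthetic_atlas <- function() {
  per_hemi <- function(hemi) {
    net <- rep("Other", 180L)
    # cardinalities split across hemispheres: 28+28 CO, 3+3 OA,
    # 12+11 DA, 25+25 FP
    net[1:28] <- "Cingulo-opercular"
    net[29:31] <- "Orbito-affective"
    n_da <- if (hemi == "L") 12L else 11L
    net[32:(31 + n_da)] <- "Dorsal attention"
    net[(32 + n_da):(31 + n_da + 25)] <- "Frontoparietal"
    data.frame(
      region_id = sprintf("%s_%03d", hemi, 1:180),
      hemisphere = hemi,
      functional_network = net,
      stringsAsFactors = FALSE
    )
  }
  atl <- rbind(per_hemi("L"), per_hemi("R"))
  rownames(atl) <- NULL
  validate_atlas(atl)
  atl
}

validate_atlas <- function(atlas, n_regions = 360L, file = NULL) {
  where <- if (is.null(file)) "atlas" else paste0("atlas file '", file, "'")
  need <- c("region_id", "hemisphere", "functional_network")
  miss <- setdiff(need, names(atlas))
  if (length(miss) > 0)
    stop(where, ": missing required column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(atlas), need)
  if (length(extra) > 0)
    stop(where, ": unknown column(s): ", paste(extra, collapse = ", "))
  if (nrow(atlas) != n_regions)
    stop(where, ": expected ", n_regions, " regions, found ", nrow(atlas))
  dup <- which(duplicated(atlas$region_id))
  if (length(dup) > 0)
    stop(where, ": duplicate region_id at line(s) ",
         paste(dup + 1L, collapse = ", "),  # +1 for the header line
         " (", paste(unique(atlas$region_id[dup]), collapse = ", "), ")")
  if (any(is.na(atlas$region_id)) || any(!nzchar(atlas$region_id)))
    stop(where, ": empty region_id")
  bad_hemi <- which(!atlas$hemisphere %in% c("L", "R"))
  if (length(bad_hemi) > 0)
    stop(where, ": hemisphere must be 'L' or 'R' at line(s) ",
         paste(bad_hemi + 1L, collapse = ", "))
  if (any(is.na(atlas$functional_network)) || any(!nzchar(atlas$functional_network)))
    stop(where, ": missing functional_network label")
  invisible(atlas)
}

#' Load a parcel atlas table
#'
#' Reads a delimited text file with columns \code{region_id},
#' \code{hemisphere} and \code{functional_network} and validates it: exactly
#' \code{n_regions} rows, unique region identifiers, one network label per
#' region. With \code{path = NULL} the bundled synthetic fixture atlas is
#' loaded (see [synthetic_atlas()]).
#'
#' @param path Path to a tab- or comma-delimited atlas table with a header, or
#'   \code{NULL} for the bundled fixture.
#' @param n_regions Expected number of regions (default 360).
#' @return A validated atlas data.frame.
#' @export
load_atlas <- function(path = NULL, n_regions = 360L) {
  if (is.null(path)) {
    path <- system.file("extdata", "synthetic_atlas_360.tsv", package = "msnet")
  }
  if (!file.exists(path)) stop("atlas file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  atl <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  validate_atlas(atl, n_regions = n_regions, file = path)
  atl
}

#' Define an analysis subnetwork by its member functional networks
#'
#' @param name Short subnetwork name, e.g. \code{"SN"} or \code{"CCN"}.
#' @param members Character vector of \code{functional_network} labels whose
#'   parcels make up the subnetwork.
#' @return An object of class \code{network_definition}.
#' @export
network_definition <- function(name, members) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop("'name' must be a single non-empty string")
  if (!is.character(members) || length(members) == 0)
    stop("network definition '", name, "' has an empty member set")
  if (anyDuplicated(members))
    stop("network definition '", name, "' lists duplicate member networks")
  structure(list(name = name, members = members),
            class = "network_definition")
}

#' Built-in salience and cognitive control network definitions
#'
#' The salience network (SN) comprises the Cingulo-opercular and
#' Orbito-affective parcels (62 nodes on the fixture atlas); the cognitive
#' control network (CCN) comprises the Dorsal attention and Frontoparietal
#' parcels (73 nodes).
#'
#' @return Named list of [network_definition()] objects.
#' @export
builtin_networks <- function() {
  list(
    SN  = network_definition("SN",  c("Cingulo-opercular", "Orbito-affective")),
    CCN = network_definition("CCN", c("Dorsal attention", "Frontoparietal"))
  )
}

#' Resolve a subnetwork to node indices
#'
#' Returns the sorted (ascending, 1-based) indices of the atlas regions whose
#' \code{functional_network} label belongs to the definition's member set. The
#' ordering is a pure function of the atlas row order, so repeated calls and
#' different platforms give identical index vectors.
#'
#' @param atlas Atlas data.frame from [load_atlas()] or [synthetic_atlas()].
#' @param definition A [network_definition()] object.
#' @return Integer vector of node indices into the atlas row order.
#' @export
#' @examples
#' atl <- synthetic_atlas()
#' length(network_nodes(atl, builtin_networks()$CCN))  # 73
network_nodes <- function(atlas, definition) {
  if (!inherits(definition, "network_definition"))
    stop("'definition' must be a network_definition object")
  unknown <- setdiff(definition$members, unique(atlas$functional_network))
  if (length(unknown) > 0)
    stop("unknown functional network label(s) for '", definition$name, "': ",
         paste(unknown, collapse = ", "))
  sort(which(atlas$functional_network %in% definition$members))
}
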
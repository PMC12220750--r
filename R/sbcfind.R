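# Species-bound clusters (SBCs). An SBC for species s is a cluster found
# anywhere in the d-hierarchy that contains every ESV assigned to s and no
# ESV assigned to any other species; unassigned ESVs may ride along. SBCs
# identify species without fixing a single global similarity threshold.

#' Threshold taxonomic assignments by species-level bootstrap
#'
#' An ESV is assigned to its classifier species call iff its species-level
#' bootstrap proportion (sBP) is at or above the threshold; below-threshold
#' or absent calls are unassigned.
#'
#' @param x an [esv_table()].
#' @param threshold sBP cutoff (default 0.8).
#' @return a `species_assignment`: named character vector esv_id -> species
#'   (NA = unassigned), with the threshold as an attribute.
#' @export
assign_species <- function(x, threshold = 0.8) {
  stopifnot(inherits(x, "esv_table"))
  sp <- ifelse(!is.na(x$esvs$sbp) & x$esvs$sbp >= threshold,
               x$esvs$species, NA_character_)
  structure(stats::setNames(sp, x$esvs$esv_id),
            threshold = threshold, class = "species_assignment")
}

#' Find species-bound clusters across the d-hierarchy
#'
#' For each assigned species, scans every partition of the hierarchy for
#' clusters containing all of that species' assigned ESVs and none assigned
#' to another species. When several distinct qualifying member-sets exist
#' (nested sets absorbing more unassigned ESVs at higher d), the set
#' persisting over the widest d range is reported (`which = "widest"`),
#' with ties broken toward more members, then lexicographically; the
#' lowest-d qualifying set is available with `which = "lowest_d"`.
#'
#' @param hierarchy an `esv_hierarchy` from [build_hierarchy()].
#' @param assignment a `species_assignment` from [assign_species()] over the
#'   same ESV set.
#' @param which rule selecting among multiple qualifying member-sets.
#' @return list of class `sbc_set`: per recovered species a record with
#'   `species`, `members`, `d_min`, `d_max`. Attributes `n_species_assigned`
#'   and `not_recovered` summarise recovery bookkeeping.
#' @export
find_sbcs <- function(hierarchy, assignment,
                      which = c("widest", "lowest_d")) {
  which <- match.arg(which)
  stopifnot(inherits(hierarchy, "esv_hierarchy"))
  ids <- names(hierarchy[[1]]$assignment)
  if (!setequal(ids, names(assignment)))
    stop("hierarchy and assignment cover different ESV sets")
  assignment <- assignment[ids]
  species <- sort(unique(assignment[!is.na(assignment)]))
  assigned_sets <- lapply(species, function(s) names(assignment)[
    !is.na(assignment) & assignment == s])
  names(assigned_sets) <- species
  all_assigned <- names(assignment)[!is.na(assignment)]

  records <- list()
  not_recovered <- character(0)
  for (s in species) {
    own <- assigned_sets[[s]]
    foreign <- setdiff(all_assigned, own)
    # per partition, the candidate cluster is the one holding this species'
    # first assigned ESV; qualification depends only on its member-set
    sets <- list()
    for (p in hierarchy) {
      cl <- p$clusters[[p$assignment[[own[1]]]]]
      if (!all(own %in% cl)) next
      if (any(foreign %in% cl)) next
      key <- paste(sort(cl), collapse = "\r")
      if (is.null(sets[[key]])) {
        sets[[key]] <- list(members = sort(cl), d_min = p$d, d_max = p$d)
      } else {
        sets[[key]]$d_max <- p$d
      }
    }
    if (!length(sets)) {
      not_recovered <- c(not_recovered, s)
      next
    }
    pick <- select_sbc_set(sets, which)
    records[[s]] <- list(species = s, members = pick$members,
                         d_min = pick$d_min, d_max = pick$d_max)
  }
  structure(unname(records), class = "sbc_set",
            n_species_assigned = length(species),
            not_recovered = not_recovered)
}

select_sbc_set <- function(sets, which) {
  if (which == "lowest_d") {
    d_mins <- vapply(sets, `[[`, integer(1), "d_min")
    return(sets[[which.min(d_mins)]])
  }
  span <- vapply(sets, function(r) r$d_max - r$d_min, integer(1))
  size <- vapply(sets, function(r) length(r$members), integer(1))
  first_id <- vapply(sets, function(r) r$members[1], character(1))
  ord <- order(-span, -size, first_id)
  sets[[ord[1]]]
}

#' @export
print.sbc_set <- function(x, ...) {
  cat("sbc_set:", length(x), "species-bound clusters (",
      attr(x, "n_species_assigned"), "species assigned,",
      length(attr(x, "not_recovered")), "not recovered )\n")
  invisible(x)
}

#' Summarise SBC recovery
#'
#' @param object an `sbc_set`.
#' @param ... unused.
#' @return data.frame with one row per SBC (species, n_members, d_min,
#'   d_max) plus recovery counts as attributes.
#' @method summary sbc_set
#' @export
summary.sbc_set <- function(object, ...) {
  df <- do.call(rbind, lapply(object, function(r)
    data.frame(species = r$species, n_members = length(r$members),
               d_min = r$d_min, d_max = r$d_max,
               stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(species = character(0), n_members = integer(0),
                     d_min = integer(0), d_max = integer(0))
  attr(df, "n_species_assigned") <- attr(object, "n_species_assigned")
  attr(df, "n_recovered") <- length(object)
  df
}

#' Merge presence columns by species-bound cluster
#'
#' One column per SBC, the OR over member ESV columns; ESVs in no SBC drop
#' out of the SBC representation. Overlapping SBC membership is an error.
#'
#' @param presence a [presence_matrix()].
#' @param sbcs an `sbc_set` from [find_sbcs()].
#' @return a [presence_matrix()] (samples x species).
#' @export
merge_presence_by_sbc <- function(presence, sbcs) {
  stopifnot(inherits(sbcs, "sbc_set"))
  members <- lapply(sbcs, `[[`, "members")
  names(members) <- vapply(sbcs, `[[`, "", "species")
  if (anyDuplicated(unlist(members)))
    stop("SBC member sets overlap")
  merge_presence_by_cluster(presence, members)
}

#' Member lists of an SBC set
#'
#' @param sbcs an `sbc_set`.
#' @return named list species -> member esv_ids.
#' @export
sbc_clusters <- function(sbcs) {
  stopifnot(inherits(sbcs, "sbc_set"))
  stats::setNames(lapply(sbcs, `[[`, "members"),
                  vapply(sbcs, `[[`, "", "species"))
}
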
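## Haplogroup frequency tabulation by region and northern/southern route
## attribution with intrusive-lineage exclusion.

ROUTE_LEVELS <- c("northern", "southern", "intrusive")

#' Construct a route assignment table
#'
#' Maps haplogroup labels to entry routes. Haplogroups absent from the table
#' inherit the nearest listed ancestor's route via the reference haplogroup
#' tree when one is supplied to [attribute_routes()].
#'
#' @param haplogroup character vector of labels.
#' @param route character vector among `"northern"`, `"southern"`,
#'   `"intrusive"`.
#' @return object of class `route_table`.
#' @export
route_table <- function(haplogroup, route) {
  stopifnot(length(haplogroup) == length(route))
  route <- as.character(route)
  bad <- setdiff(unique(route), ROUTE_LEVELS)
  if (length(bad)) stop("unknown routes: ", paste(bad, collapse = ", "))
  if (anyDuplicated(haplogroup)) stop("duplicate haplogroup in route table")
  structure(list(assignments = stats::setNames(route,
                                               as.character(haplogroup))),
            class = "route_table")
}

#' Read a route table from TSV (columns `haplogroup`, `route`)
#' @param path TSV path.
#' @return a `route_table`.
#' @export
read_route_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("haplogroup", "route") %in% names(tab)))
  route_table(tab$haplogroup, tab$route)
}

#' Read region-specific route overrides (columns `region_label`,
#' `haplogroup`, `route`)
#' @param path TSV path.
#' @return data.frame usable as `region_overrides`.
#' @export
read_route_overrides <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("region_label", "haplogroup", "route") %in% names(tab)))
  tab
}

## Resolve one haplogroup to a route: exact match, else nearest listed
## ancestor in the reference tree; NA when unresolvable.
resolve_route <- function(haplogroup, routes, ref_tree = NULL) {
  a <- routes$assignments
  l <- haplogroup
  repeat {
    if (l %in% names(a)) return(unname(a[[l]]))
    if (is.null(ref_tree) || !l %in% ref_tree$labels) return(NA_character_)
    l <- ref_tree$parents[[l]]
    if (is.na(l)) return(NA_character_)
  }
}

#' Per-region haplogroup frequency table
#'
#' @param samples data.frame with columns `sample_id`, `region_label`,
#'   `haplogroup` (nonempty; sample ids unique).
#' @return data.frame with columns `region_label`, `haplogroup`, `n`, `pct`
#'   (percentage within region), ordered by region then descending count
#'   then label.
#' @export
haplogroup_frequencies <- function(samples) {
  stopifnot(is.data.frame(samples), nrow(samples) >= 1L,
            all(c("sample_id", "region_label", "haplogroup") %in%
                names(samples)))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  agg <- stats::aggregate(list(n = samples$sample_id),
                          by = list(region_label = samples$region_label,
                                    haplogroup = samples$haplogroup),
                          FUN = length)
  tot <- stats::aggregate(list(n_region = agg$n),
                          by = list(region_label = agg$region_label),
                          FUN = sum)
  agg <- merge(agg, tot, by = "region_label")
  agg$pct <- 100 * agg$n / agg$n_region
  agg <- agg[order(agg$region_label, -agg$n, agg$haplogroup), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("region_label", "haplogroup", "n", "pct")]
}

#' Attribute samples to northern/southern entry routes by region
#'
#' Every sample's haplogroup is resolved to a route via the route table
#' (with ancestor inheritance through the reference tree), after applying
#' any region-specific overrides (e.g. a haplogroup intrusive in one region
#' but a founder in another). Intrusive samples are excluded from the
#' denominator of the route fractions but reported both as a count and as a
#' percentage of the region total. Unresolvable haplogroups raise an error
#' listing the labels.
#'
#' @param samples data.frame with columns `sample_id`, `region_label`,
#'   `haplogroup`.
#' @param routes a `route_table`.
#' @param ref_tree optional `haplogroup_tree` for ancestor inheritance.
#' @param region_overrides optional data.frame with columns `region_label`,
#'   `haplogroup`, `route`.
#' @return data.frame of class `region_summary` with one row per region:
#'   `region_label`, `n_total`, `n_intrusive`, `pct_intrusive_of_total`,
#'   `pct_northern`, `pct_southern` (of nonintrusive lineages; `NA` and
#'   `flag` set when all samples are intrusive), and rounded display
#'   percentages `pct_northern_display`, `pct_southern_display` (half-up).
#' @export
attribute_routes <- function(samples, routes, ref_tree = NULL,
                             region_overrides = NULL) {
  stopifnot(is.data.frame(samples), nrow(samples) >= 1L,
            inherits(routes, "route_table"))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  route <- character(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    r <- NA_character_
    if (!is.null(region_overrides)) {
      hit <- region_overrides$region_label == samples$region_label[i] &
        region_overrides$haplogroup == samples$haplogroup[i]
      if (any(hit)) r <- region_overrides$route[which(hit)[1L]]
    }
    if (is.na(r)) r <- resolve_route(samples$haplogroup[i], routes, ref_tree)
    route[i] <- r
  }
  if (anyNA(route))
    stop("unresolvable haplogroups: ",
         paste(sort(unique(samples$haplogroup[is.na(route)])),
               collapse = ", "))
  rows <- lapply(sort(unique(samples$region_label)), function(rg) {
    rt <- route[samples$region_label == rg]
    n_total <- length(rt)
    n_int <- sum(rt == "intrusive")
    n_non <- n_total - n_int
    pn <- if (n_non) 100 * sum(rt == "northern") / n_non else NA_real_
    ps <- if (n_non) 100 * sum(rt == "southern") / n_non else NA_real_
    data.frame(region_label = rg, n_total = n_total, n_intrusive = n_int,
               pct_intrusive_of_total = 100 * n_int / n_total,
               pct_northern = pn, pct_southern = ps,
               pct_northern_display = round_half_up(pn),
               pct_southern_display = round_half_up(ps),
               flag = if (n_non) NA_character_ else
                 "all samples intrusive: route fractions undefined",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("region_summary", class(out))
  out
}

round_half_up <- function(x) {
  ifelse(is.na(x), NA_real_, floor(x + 0.5))
}

#' Write region route summaries
#' @param summary a `region_summary` data.frame.
#' @param path output TSV path.
#' @return the data.frame, invisibly.
#' @export
write_region_summary <- function(summary, path) {
  utils::write.table(as.data.frame(summary), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(summary)
}
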
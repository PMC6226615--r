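#' @include AllClasses.R constructors.R utils.R
NULL

PARTNER_CATEGORIES <- c("uniglomerular_PN", "inhibitory_PN", "MBON",
                        "LH_local", "LH_output_reciprocal",
                        "other/undefined")

linksInNeuropil <- function(table, neuropil = NULL) {
  lk <- table@links
  if (is.null(neuropil)) return(lk)
  known <- unique(table@connectors$neuropil)
  bad <- setdiff(neuropil, known)
  if (length(bad))
    stop("unknown neuropil label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cid <- table@connectors$connector_id[table@connectors$neuropil %in%
                                         neuropil]
  lk[lk$connector_id %in% cid, , drop = FALSE]
}

#' Partner breakdown of a neuron's connectivity
#'
#' Counts a target neuron's synaptic links per partner (or per partner
#' category when \code{categories} maps partner ids to the six major
#' groups), restricted to connectors in the given neuropil. Fractions are
#' link counts over the target's total links of that direction in that
#' neuropil, so an exhaustive partition sums to 1 — each postsynaptic link
#' of a polyadic connector counts individually.
#'
#' @param table a \linkS4class{ConnectorTable}.
#' @param target neuron id.
#' @param direction \code{"incoming"} (partners presynaptic to the target)
#'   or \code{"outgoing"}.
#' @param neuropil optional neuropil label(s) to restrict to.
#' @param categories optional named character vector mapping partner neuron
#'   ids to categories; unmapped partners fall into
#'   \code{"other/undefined"}.
#' @return data.frame \code{partner, count, fraction}, descending count.
#' @export
partnerCounts <- function(table, target,
                          direction = c("incoming", "outgoing"),
                          neuropil = NULL, categories = NULL) {
  direction <- match.arg(direction)
  lk <- linksInNeuropil(table, neuropil)
  if (!target %in% lk$neuron_id && !target %in% table@links$neuron_id)
    stop("target '", target, "' not present in table", call. = FALSE)
  myRole <- if (direction == "incoming") "post" else "pre"
  partnerRole <- if (direction == "incoming") "pre" else "post"
  mine <- lk[lk$neuron_id == target & lk$role == myRole, , drop = FALSE]
  total <- nrow(mine)
  partners <- lk[lk$role == partnerRole, , drop = FALSE]
  m <- merge(mine["connector_id"], partners, by = "connector_id")
  who <- m$neuron_id
  if (!is.null(categories)) {
    who <- unname(categories[who])
    who[is.na(who)] <- "other/undefined"
  }
  tab <- sort(table(who), decreasing = TRUE)
  data.frame(partner = names(tab), count = as.integer(tab),
             fraction = as.integer(tab) / total, stringsAsFactors = FALSE)
}

#' Polyadic fan-out statistics of a neuron's presynapses
#'
#' Per-connector postsynaptic-link counts for the neuron's presynaptic
#' connectors in a region, summarized as mean and sample SD — the
#' "each presynapse was polyadic, connecting to 7.8 +- 4.6 targets" style
#' summary.
#'
#' @param table a \linkS4class{ConnectorTable}.
#' @param neuron presynaptic neuron id.
#' @param neuropil optional restriction.
#' @return list \code{mean, sd, n, fanouts}.
#' @export
polyadicStats <- function(table, neuron, neuropil = NULL) {
  lk <- linksInNeuropil(table, neuropil)
  preConn <- lk$connector_id[lk$neuron_id == neuron & lk$role == "pre"]
  if (!length(preConn))
    stop("neuron '", neuron, "' has no presynapses in the region",
         call. = FALSE)
  post <- lk[lk$role == "post" & lk$connector_id %in% preConn, ,
             drop = FALSE]
  fan <- as.integer(table(factor(post$connector_id, levels = preConn)))
  list(mean = mean(fan), sd = stats::sd(fan), n = length(fan),
       fanouts = fan)
}

#' Bounds on a partner's share of direct excitation
#'
#' Known-excitatory input categories are the uniglomerular PNs and MBONs;
#' inputs of unknown sign dilute the denominator. The focal category's
#' share of direct excitation is therefore bracketed by
#' \code{upper = 100 * focal / excitatory} and
#' \code{lower = 100 * focal / (excitatory + undefined)}.
#'
#' @param fractions named numeric of input fractions (or counts) per
#'   category; names from \code{partnerCounts} categories.
#' @param focal the focal excitatory category (e.g. \code{"MBON"}).
#' @param excitatory categories counted as known-excitatory.
#' @param undefined the unknown-sign category name.
#' @return c(lower, upper) in percent.
#' @examples
#' excitatoryShareBounds(c(uniglomerular_PN = 26.5, MBON = 4.6,
#'                         `other/undefined` = 15.6), "MBON")
#' @export
excitatoryShareBounds <- function(fractions, focal = "MBON",
                                  excitatory = c("uniglomerular_PN", "MBON"),
                                  undefined = "other/undefined") {
  focalVal <- if (focal %in% names(fractions)) fractions[[focal]] else 0
  if (focalVal == 0) return(c(lower = 0, upper = 0))
  excTot <- sum(fractions[names(fractions) %in% excitatory])
  undTot <- sum(fractions[names(fractions) %in% undefined])
  if (excTot <= 0) stop("no known-excitatory input", call. = FALSE)
  c(lower = 100 * focalVal / (excTot + undTot),
    upper = 100 * focalVal / excTot)
}

#' Input heatmap matrices across targets and partner groups
#'
#' Per-target-per-group synapse counts (incoming links), with a companion
#' matrix normalized by each target's total postsynapse count in its
#' neuropil. Groups with no connectivity anywhere are dropped, and both
#' rows and columns are ordered by descending total count.
#'
#' @param table a \linkS4class{ConnectorTable}.
#' @param targets character vector of target neuron ids.
#' @param groupBy named character vector mapping partner neuron ids to
#'   groups (e.g. PN ids to glomeruli); unmapped partners are dropped.
#' @param neuropils neuropil label(s); one column per target x neuropil.
#' @return list with \code{counts} and \code{normalized} matrices
#'   (rows = groups, columns = \code{target|neuropil}).
#' @export
connectivityHeatmap <- function(table, targets, groupBy,
                                neuropils = unique(connectors(table)$neuropil)) {
  groups <- sort(unique(unname(groupBy)))
  cols <- as.vector(outer(targets, neuropils, paste, sep = "|"))
  counts <- matrix(0L, length(groups), length(cols),
                   dimnames = list(groups, cols))
  norm <- matrix(0, length(groups), length(cols),
                 dimnames = list(groups, cols))
  for (np in neuropils) {
    lk <- linksInNeuropil(table, np)
    for (tg in targets) {
      mine <- lk[lk$neuron_id == tg & lk$role == "post", , drop = FALSE]
      denom <- nrow(mine)
      pre <- lk[lk$role == "pre", , drop = FALSE]
      m <- merge(mine["connector_id"], pre, by = "connector_id")
      grp <- unname(groupBy[m$neuron_id])
      tab <- table(factor(grp[!is.na(grp)], levels = groups))
      cn <- paste(tg, np, sep = "|")
      counts[, cn] <- as.integer(tab)
      norm[, cn] <- if (denom > 0) as.integer(tab) / denom else 0
    }
  }
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  norm <- norm[keep, , drop = FALSE]
  ro <- order(-rowSums(counts))
  co <- order(-colSums(counts))
  list(counts = counts[ro, co, drop = FALSE],
       normalized = norm[ro, co, drop = FALSE])
}
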
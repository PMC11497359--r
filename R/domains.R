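#' Build a named-domain map from chain-scoped residue ranges
#'
#' A domain map partitions (part of) a structure into named domains, each a
#' set of inclusive 1-based residue-id intervals on one chain. Within a chain
#' no residue may belong to two domains.
#'
#' @param spec A data frame with columns `domain`, `chain`, `start`, `end`
#'   (one row per interval), or a list of `list(domain =, chain =, ranges =
#'   list(c(lo, hi), ...))` entries.
#' @return A tibble of class `domain_map` with columns `domain`, `chain`,
#'   `start`, `end`.
#' @export
#' @examples
#' build_domain_map(data.frame(
#'   domain = c("D1", "D2"), chain = "A", start = c(1, 11), end = c(10, 20)
#' ))
build_domain_map <- function(spec) {
  if (!is.data.frame(spec)) {
    spec <- purrr::map_dfr(spec, function(e) {
      tibble::tibble(
        domain = e$domain, chain = e$chain,
        start = purrr::map_dbl(e$ranges, 1),
        end = purrr::map_dbl(e$ranges, 2)
      )
    })
  }
  spec <- tibble::as_tibble(spec)
  stopifnot(all(c("domain", "chain", "start", "end") %in% names(spec)))
  spec <- dplyr::mutate(
    spec,
    domain = as.character(.data$domain),
    chain = as.character(.data$chain),
    start = as.integer(.data$start),
    end = as.integer(.data$end)
  )
  if (any(spec$start > spec$end)) {
    bad <- which(spec$start > spec$end)[1]
    stop("Interval with start > end: [", spec$start[bad], ", ", spec$end[bad],
         "] in domain '", spec$domain[bad], "'.", call. = FALSE)
  }
  # overlap check by enumerating residue ids per chain
  per_chain <- spec |>
    dplyr::mutate(ids = purrr::map2(.data$start, .data$end, seq)) |>
    tidyr::unnest("ids") |>
    dplyr::group_by(.data$chain, .data$ids) |>
    dplyr::filter(dplyr::n() > 1L) |>
    dplyr::ungroup()
  if (nrow(per_chain) > 0L) {
    clash <- sort(unique(per_chain$ids))
    shown <- utils::head(clash, 10L)
    stop(
      "Domains overlap on chain ", per_chain$chain[1], ": residue id(s) ",
      paste(shown, collapse = ", "),
      if (length(clash) > length(shown)) sprintf(" (and %d more)", length(clash) - length(shown)),
      ".",
      call. = FALSE
    )
  }
  structure(
    dplyr::arrange(spec, .data$chain, .data$start),
    class = c("domain_map", class(tibble::tibble()))
  )
}

#' The four-domain integrin fragment map
#'
#' Convenience constructor for the domain partition of the integrin fragment
#' analysed throughout the package's examples: on chain A the N domain
#' (residues 1-126 and 328-597) and the alpha-1 domain (127-327); on chain B
#' the hybrid domain (58-101 and 343-423) and the beta-1 domain (102-342).
#'
#' @return A `domain_map` with domains `N`, `alpha1`, `Hyb`, `beta1`.
#' @export
integrin_domain_map <- function() {
  build_domain_map(tibble::tibble(
    domain = c("N", "N", "alpha1", "Hyb", "Hyb", "beta1"),
    chain = c("A", "A", "A", "B", "B", "B"),
    start = c(1, 328, 127, 58, 343, 102),
    end = c(126, 597, 327, 101, 423, 342)
  ))
}

#' Look up the domain of residues
#'
#' @param map A `domain_map`.
#' @param chain Character vector of chain identifiers.
#' @param residue_id Integer vector of residue ids (recycled against `chain`).
#' @return Character vector of domain labels; `NA` for residues outside all
#'   ranges.
#' @export
assign_residue_domain <- function(map, chain, residue_id) {
  stopifnot(inherits(map, "domain_map"))
  n <- max(length(chain), length(residue_id))
  chain <- rep_len(as.character(chain), n)
  residue_id <- rep_len(as.integer(residue_id), n)
  out <- rep(NA_character_, n)
  for (i in seq_len(nrow(map))) {
    hit <- chain == map$chain[i] &
      residue_id >= map$start[i] & residue_id <= map$end[i]
    out[hit] <- map$domain[i]
  }
  out
}

#' Enumerate the residues of a domain
#'
#' @param map A `domain_map`.
#' @param domain Domain label present in `map`.
#' @return A tibble with columns `chain`, `residue_id`.
#' @export
domain_residues <- function(map, domain) {
  stopifnot(inherits(map, "domain_map"))
  rows <- map[map$domain == domain, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("Domain '", domain, "' is not in the map.", call. = FALSE)
  }
  rows |>
    dplyr::mutate(residue_id = purrr::map2(.data$start, .data$end, seq)) |>
    tidyr::unnest("residue_id") |>
    dplyr::select("chain", "residue_id")
}

#' @export
print.domain_map <- function(x, ...) {
  sizes <- x |>
    dplyr::group_by(.data$domain) |>
    dplyr::summarise(n = sum(.data$end - .data$start + 1L), .groups = "drop")
  cat("<domain_map> ", nrow(sizes), " domain(s): ",
      paste(sprintf("%s (%d res)", sizes$domain, sizes$n), collapse = ", "),
      "\n", sep = "")
  NextMethod()
}
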
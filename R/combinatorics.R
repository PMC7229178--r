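#' Hexamer arrangement counting
#'
#' CRAC channels are hexamers assembled from up to three ORAI isoforms. How
#' many distinct channels can be built depends on which arrangements are
#' considered equivalent. Four symmetry conventions are supported:
#'
#' * `"bracelet"` — position on the hexagonal ring matters, but arrangements
#'   related by any of the 12 dihedral symmetries (6 rotations + 6
#'   reflections) are identified. This is the convention behind the published
#'   Burnside counts (92 channels for 3 isoforms).
#' * `"necklace"` — rotations only (a membrane-embedded ring arguably cannot
#'   be flipped); 6 symmetries.
#' * `"multiset"` — only subunit stoichiometry matters (e.g. 131313 and
#'   113133 are the same channel); counted by stars and bars.
#' * `"fixed"` — every labelled sequence is distinct.
#'
#' `count_arrangements()` applies Burnside's Lemma: the number of orbits is
#' the average, over the symmetry group, of the number of colorings fixed by
#' each group element; a permutation with `c` cycles fixes `n^c` colorings.
#' For the hexagon the rotation cycle counts are 6,1,2,3,2,1 and the
#' reflections contribute three axes through opposite vertices (4 cycles) and
#' three through edge midpoints (3 cycles).
#'
#' @param n_colors number of isoform types available (positive integer).
#' @param mode symmetry convention, one of `"bracelet"`, `"necklace"`,
#'   `"multiset"`, `"fixed"`.
#' @return `count_arrangements()`: a single non-negative integer.
#' @examples
#' count_arrangements(3, "bracelet")  # 92 distinct heteromeric channels
#' count_arrangements(3, "multiset")  # 28 stoichiometries
#' count_exact_palette(3, 3, "bracelet")  # 56 use all three isoforms
#' @export
count_arrangements <- function(n_colors, mode = c("bracelet", "necklace", "multiset", "fixed")) {
  mode <- match.arg(mode)
  if (length(n_colors) != 1L || !is.finite(n_colors) || n_colors < 1 ||
      n_colors != round(n_colors)) {
    stop("`n_colors` must be a single positive integer")
  }
  n <- as.numeric(n_colors)
  count <- switch(mode,
    fixed    = n^6,
    multiset = choose(n + 5, 6),
    necklace = {
      s <- n^6 + 2 * n + 2 * n^2 + n^3
      stopifnot(s %% 6 == 0)
      s / 6
    },
    bracelet = {
      # rotations: n^6 + 2n + 2n^2 + n^3; reflections: 3n^3 + 3n^4
      s <- n^6 + 2 * n + 2 * n^2 + n^3 + 3 * n^3 + 3 * n^4
      stopifnot(s %% 12 == 0)
      s / 12
    }
  )
  as.integer(count)
}

#' @rdname count_arrangements
#' @param k_used number of distinct isoform types that must each appear at
#'   least once in the hexamer.
#' @param n_available number of isoform types to draw the palette from
#'   (`k_used <= n_available <= 6`).
#' @return `count_exact_palette()`: the number of arrangements using exactly
#'   `k_used` distinct types chosen among `n_available`, i.e.
#'   `choose(n_available, k_used)` times the per-palette inclusion-exclusion
#'   count `sum_j (-1)^j choose(k, j) count(k - j)`.
#' @export
count_exact_palette <- function(k_used, n_available,
                                mode = c("bracelet", "necklace", "multiset", "fixed")) {
  mode <- match.arg(mode)
  if (k_used < 1 || k_used != round(k_used)) stop("`k_used` must be a positive integer")
  if (k_used > 6) stop("at most 6 positions: `k_used` cannot exceed 6")
  if (n_available < k_used) stop("`n_available` must be at least `k_used`")
  j <- 0:(k_used - 1)
  per_palette <- sum((-1)^j * choose(k_used, j) *
                       vapply(k_used - j, count_arrangements, numeric(1), mode = mode))
  as.integer(choose(n_available, k_used) * per_palette)
}

#' @rdname count_arrangements
#' @return `enumerate_arrangements()`: a character vector of canonical
#'   representatives, one per equivalence class, each a 6-letter string over
#'   `LETTERS[1:n_colors]`. The representative is the lexicographically
#'   smallest image under the mode's group, so the output is deterministic.
#'   Enumeration is refused for `n_colors > 4` (4^6 labellings is the guard).
#' @export
enumerate_arrangements <- function(n_colors, mode = c("bracelet", "necklace", "multiset", "fixed")) {
  mode <- match.arg(mode)
  if (n_colors < 1 || n_colors != round(n_colors)) stop("`n_colors` must be a positive integer")
  if (n_colors > 4) stop("enumeration refused for more than 4 colors")
  cols <- LETTERS[seq_len(n_colors)]
  grid <- as.matrix(expand.grid(rep(list(cols), 6), stringsAsFactors = FALSE))
  canon <- apply(grid, 1L, canonical_arrangement, mode = mode)
  sort(unique(canon))
}

# group images of a length-6 sequence for each symmetry convention
hexamer_group_images <- function(x, mode) {
  rot <- function(s, k) s[((seq_along(s) - 1 + k) %% 6) + 1]
  switch(mode,
    fixed    = list(x),
    multiset = list(sort(x)),
    necklace = lapply(0:5, rot, s = x),
    bracelet = c(lapply(0:5, rot, s = x),
                 lapply(0:5, rot, s = rev(x)))
  )
}

canonical_arrangement <- function(x, mode) {
  imgs <- vapply(hexamer_group_images(x, mode), paste0, character(1), collapse = "")
  min(imgs)
}
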
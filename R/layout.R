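#' Build a 1536-colony plate layout
#'
#' Lays ORFs out on 32 x 48 plates with a 4-deep border of dummy colonies and
#' one replicate group per ORF. Two group geometries are supported:
#'
#' * `"fluor4x4"` — the colony-fluorescence design: a 4 x 4 group holding
#'   6 OsTIR1+ sample replicates, 3 OsTIR1- sample replicates, 3
#'   non-fluorescent background colonies and 4 fluorescent reference colonies
#'   (60 groups per plate).
#' * `"fitness2x2"` — the fitness-screen design: 4 technical replicates of one
#'   strain in a 2 x 2 group (240 groups per plate).
#'
#' @param n_orfs Number of ORFs to place (one group each).
#' @param group Group geometry, `"fluor4x4"` or `"fitness2x2"`.
#' @param n_plates Number of plates to use; defaults to the minimum needed.
#'   An explicit value smaller than that is an error naming the requirement.
#' @param border Depth of the dummy border, default 4.
#' @param seed Optional integer; when given, ORFs are assigned to groups in a
#'   reproducibly shuffled order instead of row-major order.
#' @return A layout data frame with columns `plate`, `row`, `col`, `orf`
#'   (`NA` outside sample positions), `role` (one of `sample_plus`,
#'   `sample_minus`, `background`, `reference`, `dummy`) and `group` (integer
#'   id, `NA` for dummy positions). Plate dimensions and geometry are attached
#'   as attributes `dim`, `border` and `group_type`.
#' @examples
#' lay <- make_layout(10, "fluor4x4")
#' table(lay$role)
#' @export
make_layout <- function(n_orfs, group = c("fluor4x4", "fitness2x2"),
                        n_plates = NULL, border = 4L, seed = NULL) {
  group <- match.arg(group)
  stopifnot(n_orfs >= 0, border >= 0)
  nr <- 32L; nc <- 48L
  ur <- nr - 2L * border   # usable rows
  uc <- nc - 2L * border   # usable cols
  if (ur <= 0L || uc <= 0L) stop("border too deep for a 32x48 plate")
  gs <- if (group == "fluor4x4") 4L else 2L
  groups_per_plate <- (ur %/% gs) * (uc %/% gs)
  need <- if (n_orfs == 0L) 1L else ceiling(n_orfs / groups_per_plate)
  if (is.null(n_plates)) n_plates <- need
  if (n_plates < need)
    stop(sprintf("capacity exceeded: %d ORFs need %d plate(s) of %d %s groups, got %d",
                 n_orfs, need, groups_per_plate, group, n_plates))

  orfs <- if (n_orfs > 0L) sprintf("ORF%04d", seq_len(n_orfs)) else character(0)
  if (!is.null(seed) && n_orfs > 1L) {
    set.seed(seed)
    orfs <- sample(orfs)
  }

  # role pattern within a group, row-major; the three strain types are
  # interleaved across rows so that local (windowed) statistics see the same
  # mix of genotypes whatever their phase relative to the group grid
  roles4 <- matrix(c("sample_plus", "sample_minus", "sample_plus", "reference",
                     "background", "sample_plus", "sample_minus", "reference",
                     "sample_plus", "background", "sample_plus", "reference",
                     "sample_minus", "sample_plus", "background", "reference"),
                   4L, 4L, byrow = TRUE)
  roles2 <- matrix("sample_plus", 2L, 2L)
  pat <- if (group == "fluor4x4") roles4 else roles2

  out <- vector("list", n_plates)
  gid <- 0L
  for (p in seq_len(n_plates)) {
    df <- expand.grid(row = seq_len(nr), col = seq_len(nc),
                      KEEP.OUT.ATTRS = FALSE)
    df <- df[order(df$row, df$col), , drop = FALSE]
    df$plate <- p
    df$orf <- NA_character_
    df$role <- "dummy"
    df$group <- NA_integer_
    for (gr in seq_len(ur %/% gs)) {
      for (gc in seq_len(uc %/% gs)) {
        gid_local <- (p - 1L) * groups_per_plate +
          (gr - 1L) * (uc %/% gs) + gc
        if (gid_local > n_orfs) next
        gid <- gid + 1L
        r0 <- border + (gr - 1L) * gs
        c0 <- border + (gc - 1L) * gs
        for (i in seq_len(gs)) {
          for (j in seq_len(gs)) {
            k <- (r0 + i - 1L) * nc + (c0 + j)  # df is row-major ordered
            df$role[k] <- pat[i, j]
            df$orf[k] <- orfs[gid_local]
            df$group[k] <- gid_local
          }
        }
      }
    }
    out[[p]] <- df
  }
  lay <- do.call(rbind, out)
  lay <- lay[, c("plate", "row", "col", "orf", "role", "group")]
  rownames(lay) <- NULL
  attr(lay, "dim_plate") <- c(nr, nc)
  attr(lay, "border") <- border
  attr(lay, "group_type") <- group
  lay
}
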
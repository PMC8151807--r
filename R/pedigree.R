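#' Validate and topologically sort a pedigree
#'
#' Checks structural integrity of a pedigree table (no self-parenting, no
#' cycles, parents consistent with their recorded sex) and returns the table
#' reordered so that every parent precedes its offspring.  All downstream
#' pedigree algebra (inbreeding, the inverse numerator relationship matrix,
#' breeding-value simulation) requires this ordering.
#'
#' @param ped data frame with columns `animal`, `sire`, `dam` (character ids,
#'   `NA` for unknown parents), and optionally `sex` (`"M"`/`"F"`),
#'   `birth_date` (`Date`), `breed_sire`, `multiple_birth`.
#' @return The pedigree sorted parents-first, with attribute `sorted = TRUE`.
#' @examples
#' ped <- data.frame(animal = c("C", "A", "B"),
#'                   sire = c("A", NA, NA), dam = c("B", NA, NA),
#'                   sex = c("F", "M", "F"))
#' validate_and_sort(ped)$animal
#' @export
validate_and_sort <- function(ped) {
  stopifnot(is.data.frame(ped), all(c("animal", "sire", "dam") %in% names(ped)))
  ped$animal <- as.character(ped$animal)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  if (anyDuplicated(ped$animal)) {
    stop("duplicated animal ids: ", paste(head(ped$animal[duplicated(ped$animal)], 5), collapse = ", "))
  }
  if (any(ped$animal == ped$sire | ped$animal == ped$dam, na.rm = TRUE)) {
    stop("self-parenting detected")
  }
  for (col in c("sire", "dam")) {
    unknown <- !is.na(ped[[col]]) & !(ped[[col]] %in% ped$animal)
    if (any(unknown)) {
      stop(sum(unknown), " ", col, " id(s) absent from the animal column; ",
           "add them as founders or set to NA (first: ",
           ped[[col]][which(unknown)[1]], ")")
    }
  }
  if (!is.null(ped$sex)) {
    sx <- ped$sex[match(ped$sire, ped$animal)]
    dx <- ped$sex[match(ped$dam, ped$animal)]
    if (any(sx == "F", na.rm = TRUE)) stop("a female animal is used as sire")
    if (any(dx == "M", na.rm = TRUE)) stop("a male animal is used as dam")
  }
  n <- nrow(ped)
  id <- ped$animal
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  # Kahn's algorithm on parent -> offspring edges
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (k in seq_len(n)) {
    if (!is.na(si[k])) children[[si[k]]] <- c(children[[si[k]]], k)
    if (!is.na(di[k])) children[[di[k]]] <- c(children[[di[k]]], k)
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) < n) {
    cyc <- setdiff(seq_len(n), order)
    stop("pedigree contains a cycle involving: ",
         paste(id[head(cyc, 10)], collapse = " -> "))
  }
  out <- ped[order, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sorted") <- TRUE
  out
}

ensure_sorted <- function(ped) {
  if (isTRUE(attr(ped, "sorted"))) ped else validate_and_sort(ped)
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes the diagonal of the numerator relationship matrix minus one for
#' every animal, i.e. Wright's inbreeding coefficient F, by the recursion of
#' Meuwissen and Luo (1992) on the L D L' decomposition of A.  Founders and
#' animals with an unknown parent contribute no inbreeding pathway through
#' that parent.
#'
#' @param ped pedigree table (sorted or not; sorted internally).
#' @return Named numeric vector of F, in the order of the sorted pedigree.
#' @export
inbreeding <- function(ped) {
  ped <- ensure_sorted(ped)
  n <- nrow(ped)
  id <- ped$animal
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  f <- numeric(n)       # F_i
  dvec <- numeric(n)    # within-family (Mendelian) variance coefficient
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    fs <- if (is.na(s)) -1 else f[s]
    fd <- if (is.na(d)) -1 else f[d]
    dvec[i] <- 0.5 - 0.25 * (fs + fd)
    if (is.na(s) || is.na(d)) { f[i] <- 0; next }
    # trace ancestors of i, accumulating L values
    AN <- i
    Lv <- numeric(n); Lv[i] <- 1
    fi <- -1
    while (length(AN)) {
      j <- max(AN)
      AN <- AN[AN != j]
      L <- Lv[j]
      sj <- si[j]; dj <- di[j]
      if (!is.na(sj)) { if (Lv[sj] == 0) AN <- c(AN, sj); Lv[sj] <- Lv[sj] + 0.5 * L }
      if (!is.na(dj)) { if (Lv[dj] == 0) AN <- c(AN, dj); Lv[dj] <- Lv[dj] + 0.5 * L }
      fi <- fi + L * L * dvec[j]
      Lv[j] <- 0
    }
    f[i] <- fi
  }
  names(f) <- id
  f
}

# Mendelian-sampling variance coefficients d_i such that |A| = prod d_i.
# Unknown parents contribute as F = -1 (i.e. d = 1 with none known,
# 0.75 - F_known/4 with one).  Used by a_inverse and the simulator.
mendelian_d <- function(ped, f = NULL) {
  ped <- ensure_sorted(ped)
  if (is.null(f)) f <- inbreeding(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  fs <- ifelse(is.na(si), -1, f[si])
  fd <- ifelse(is.na(di), -1, f[di])
  d <- 0.5 - 0.25 * (fs + fd)
  names(d) <- ped$animal
  d
}

#' Assign unknown-parent genetic groups
#'
#' Every unknown sire or dam slot of the pedigree is mapped to a genetic
#' group, the fixed effect that absorbs genetic-level differences among the
#' base populations the unknown parents came from.  Two policies are
#' provided. `"dataset2"` defines two groups: group `"G1"` for animals with
#' only the dam unknown and `"G2"` for animals with the sire (or both
#' parents) unknown.  `"dataset1"` partitions unknown-parent slots by sex of
#' the animal, birth-year bin, which parent is unknown, and breed-of-sire
#' code (non-Holstein breeds get their own groups); sparse birth years are
#' merged forward until each group reaches `min_group_size`.
#'
#' @param ped pedigree table.
#' @param rule `"dataset2"` (two groups) or `"dataset1"` (many groups).
#' @param min_group_size minimum animals per group for the `"dataset1"`
#'   year-bin merging.
#' @param holstein_code breed-of-sire code treated as the main population.
#' @return data frame (`animal`, `slot`, `group`) with one row per unknown
#'   parent slot, plus attribute `groups` listing group labels. Zero rows if
#'   all parents are known.
#' @export
assign_groups <- function(ped, rule = c("dataset2", "dataset1"),
                          min_group_size = 50L, holstein_code = "HOL") {
  rule <- match.arg(rule)
  ped <- ensure_sorted(ped)
  miss_s <- is.na(ped$sire)
  miss_d <- is.na(ped$dam)
  idx <- which(miss_s | miss_d)
  if (!length(idx)) {
    out <- data.frame(animal = character(0), slot = character(0),
                      group = character(0), stringsAsFactors = FALSE)
    attr(out, "groups") <- character(0)
    return(out)
  }
  rows <- data.frame(
    animal = rep(ped$animal[idx], times = miss_s[idx] + miss_d[idx]),
    slot = unlist(lapply(idx, function(i)
      c(if (miss_s[i]) "sire", if (miss_d[i]) "dam"))),
    stringsAsFactors = FALSE)
  i <- match(rows$animal, ped$animal)
  if (rule == "dataset2") {
    pat_dam_only <- !miss_s[i] & miss_d[i]
    rows$group <- ifelse(pat_dam_only, "G1", "G2")
  } else {
    sex <- if (is.null(ped$sex)) "U" else ped$sex[i]
    yr <- if (is.null(ped$birth_date)) 0L else
      as.integer(format(as.Date(ped$birth_date[i]), "%Y"))
    brd <- if (is.null(ped$breed_sire)) holstein_code else
      ifelse(is.na(ped$breed_sire[i]), holstein_code, ped$breed_sire[i])
    pat <- ifelse(miss_s[i] & miss_d[i], "both",
                  ifelse(miss_s[i], "sire", "dam"))
    # merge sparse years within (sex, pattern, breed) strata
    strat <- paste(sex, pat, brd, sep = "|")
    yrbin <- yr
    for (s in unique(strat)) {
      sel <- strat == s
      tb <- sort(unique(yrbin[sel]))
      counts <- vapply(tb, function(y) sum(sel & yrbin == y), integer(1))
      merged <- tb
      acc <- 0L; start <- tb[1]
      for (k in seq_along(tb)) {
        acc <- acc + counts[k]
        merged[k] <- start
        if (acc >= min_group_size) { acc <- 0L; if (k < length(tb)) start <- tb[k + 1] }
      }
      if (acc > 0L && length(tb) > 1L) {
        # fold a trailing underfull bin into the previous one
        last_start <- merged[length(tb)]
        prev <- merged[merged != last_start]
        if (length(prev)) merged[merged == last_start] <- max(prev)
      }
      yrbin[sel] <- merged[match(yrbin[sel], tb)]
    }
    rows$group <- paste0("G_", sex, "_", yrbin, "_", pat, "_", brd)
  }
  attr(rows, "groups") <- sort(unique(rows$group))
  rows
}

#' Inverse of the (group-augmented) numerator relationship matrix
#'
#' Builds A-inverse directly by Henderson's rules with the Mendelian-sampling
#' variances corrected for parental inbreeding.  When a group assignment is
#' supplied, unknown parent slots are replaced by their genetic groups
#' (phantom-parent augmentation), so the returned matrix spans animals plus
#' groups and the mixed-model equations deliver group solutions alongside
#' breeding values.
#'
#' @param ped pedigree table.
#' @param groups optional group assignment from [assign_groups()].
#' @param f optional precomputed inbreeding coefficients.
#' @return Sparse symmetric matrix (`dsCMatrix`) with dimnames
#'   `c(animals, groups)` in sorted pedigree order.
#' @export
a_inverse <- function(ped, groups = NULL, f = NULL) {
  ped <- ensure_sorted(ped)
  n <- nrow(ped)
  id <- ped$animal
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  d <- mendelian_d(ped, f)
  glab <- if (is.null(groups)) character(0) else attr(groups, "groups")
  ng <- length(glab)
  if (ng) {
    gs <- groups[groups$slot == "sire", ]
    gd <- groups[groups$slot == "dam", ]
    si[is.na(si)] <- n + match(gs$group[match(id[is.na(si)], gs$animal)], glab)
    di[is.na(di)] <- n + match(gd$group[match(id[is.na(di)], gd$animal)], glab)
    if (anyNA(si) || anyNA(di)) stop("group assignment does not cover every unknown parent slot")
  }
  alpha <- 1 / d
  ii <- jj <- integer(0); xx <- numeric(0)
  # triplets, lower storage handled by forceSymmetric at the end
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  ai <- seq_len(n)
  add(ai, ai, alpha)
  for (slot in list(si, di)) {
    k <- !is.na(slot)
    add(ai[k], slot[k], -alpha[k] / 2)
    add(slot[k], ai[k], -alpha[k] / 2)
    add(slot[k], slot[k], alpha[k] / 4)
  }
  k <- !is.na(si) & !is.na(di)
  add(si[k], di[k], alpha[k] / 4)
  add(di[k], si[k], alpha[k] / 4)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n + ng, n + ng),
                            dimnames = list(c(id, glab), c(id, glab)))
  Matrix::forceSymmetric(Matrix::drop0(A))
}

#' Dense numerator relationship matrix by the tabular method
#'
#' Recursive tabular construction of A for small pedigrees.  Quadratic in
#' pedigree size; intended for reporting and for cross-checks of the sparse
#' [a_inverse()] path, not for production evaluation.
#'
#' @param ped pedigree table.
#' @return Dense symmetric matrix with animal dimnames.
#' @export
a_matrix <- function(ped) {
  ped <- ensure_sorted(ped)
  n <- nrow(ped)
  id <- ped$animal
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    for (j in seq_len(i - 1L)) {
      a <- 0
      if (!is.na(s)) a <- a + 0.5 * A[j, s]
      if (!is.na(d)) a <- a + 0.5 * A[j, d]
      A[i, j] <- A[j, i] <- a
    }
  }
  A
}

# Fraction-of-genes matrix Q (animals x groups): expected contribution of
# each genetic group to each animal, by the recursion Q_i = (Q_s + Q_d)/2
# with unknown slots pointing at their group.  Used to carry groups as
# fixed covariates in REML and as a dense oracle for the phantom-parent
# augmentation.
group_covariates <- function(ped, groups) {
  ped <- ensure_sorted(ped)
  glab <- attr(groups, "groups")
  n <- nrow(ped)
  Q <- matrix(0, n, length(glab), dimnames = list(ped$animal, glab))
  if (!length(glab)) return(Q)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  gs <- groups[groups$slot == "sire", ]
  gd <- groups[groups$slot == "dam", ]
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      g <- gs$group[match(ped$animal[i], gs$animal)]
      Q[i, g] <- Q[i, g] + 0.5
    } else Q[i, ] <- Q[i, ] + 0.5 * Q[si[i], ]
    if (is.na(di[i])) {
      g <- gd$group[match(ped$animal[i], gd$animal)]
      Q[i, g] <- Q[i, g] + 0.5
    } else Q[i, ] <- Q[i, ] + 0.5 * Q[di[i], ]
  }
  Q
}
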
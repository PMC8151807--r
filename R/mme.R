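# Mixed-model equations for the repeatability animal model
#
#   yg = HYS + age(sqrt, linear, quadratic) + genetic group + u + pe + e
#
# HYS, age and groups fixed; u ~ A sigma2_a, pe ~ I sigma2_p (sex-specific
# allowed), e ~ W^-1 sigma2_e with per-record weights W realizing
# heterogeneous residual variances on a common reference scale.
#
# Two treatments of unknown-parent groups are supported:
#  * "augment":   phantom-parent augmentation of A-inverse; group solutions
#                 share the additive block (used for genetic evaluation);
#  * "covariate": expected group fractions Q enter the fixed part (used by
#                 REML, where the likelihood requires a plain A).

#' Build the design components of the mixed-model equations
#'
#' @param records edited record table from [apply_edits()] (columns `animal`,
#'   `yg`, `age`, `hys`, `sex`).
#' @param ped pedigree table.
#' @param groups optional [assign_groups()] result.
#' @param group_mode `"augment"` or `"covariate"` (see above).
#' @param center_age age at which the age covariates are centred (days);
#'   affects only the intercept interpretation.
#' @return An opaque list consumed by [solve_mme()] and [reml_estimate()].
#' @export
mme_system <- function(records, ped, groups = NULL,
                       group_mode = c("augment", "covariate"),
                       center_age = 365) {
  group_mode <- match.arg(group_mode)
  ped <- ensure_sorted(ped)
  stopifnot(all(c("animal", "yg", "age", "hys", "sex") %in% names(records)))
  if (!all(records$animal %in% ped$animal))
    stop("records reference animals absent from the pedigree")
  nrec <- nrow(records)
  if (!nrec) stop("no records")

  hys <- factor(records$hys)
  a <- records$age
  Xage <- cbind(sqrt_age = sqrt(a) - sqrt(center_age),
                age = a - center_age,
                age2 = a^2 - center_age^2)
  Xhys <- Matrix::sparseMatrix(i = seq_len(nrec), j = as.integer(hys), x = 1,
                               dims = c(nrec, nlevels(hys)),
                               dimnames = list(NULL, paste0("hys:", levels(hys))))
  X <- cbind(methods::as(Matrix::Matrix(Xage, sparse = TRUE), "CsparseMatrix"), Xhys)

  has_groups <- !is.null(groups) && nrow(groups) > 0
  glab <- if (has_groups) attr(groups, "groups") else character(0)
  if (group_mode == "covariate" && has_groups && length(glab) > 1) {
    Q <- group_covariates(ped, groups)
    Qrec <- Q[match(records$animal, ped$animal), -length(glab), drop = FALSE]
    colnames(Qrec) <- paste0("group:", glab[-length(glab)])
    X <- cbind(X, methods::as(Matrix::Matrix(Qrec, sparse = TRUE), "CsparseMatrix"))
  }

  # constant covariate columns (e.g. age terms when every record shares one
  # age) carry no information and would make the equations singular
  const_col <- Matrix::colSums(X != 0) == 0
  if (any(const_col)) {
    message("dropping ", sum(const_col), " empty fixed-effect column(s): ",
            paste(colnames(X)[const_col], collapse = ", "))
    X <- X[, !const_col, drop = FALSE]
  }

  augment <- group_mode == "augment" && has_groups
  ainv <- a_inverse(ped, groups = if (augment) groups else NULL)
  if (augment) {
    # one genetic group is confounded with the contemporary-group mean, so
    # the last group is the reference (solution 0); group solutions and
    # EBVs are expressed relative to it (the base adjustment re-centres)
    ref <- nrow(ainv)
    ainv <- ainv[-ref, -ref, drop = FALSE]
  }
  add_ids <- rownames(ainv)               # animals then (maybe) groups
  n_add <- length(add_ids)
  ja <- match(records$animal, add_ids)
  Za <- Matrix::sparseMatrix(i = seq_len(nrec), j = ja, x = 1,
                             dims = c(nrec, n_add))

  pe_ids <- sort(unique(records$animal))
  jp <- match(records$animal, pe_ids)
  Zp <- Matrix::sparseMatrix(i = seq_len(nrec), j = jp, x = 1,
                             dims = c(nrec, length(pe_ids)))
  pe_sex <- records$sex[match(pe_ids, records$animal)]

  list(y = records$yg, X = X, Za = Za, Zp = Zp, ainv = ainv,
       f = inbreeding(ped),
       add_ids = add_ids, n_animals = nrow(ped), n_groups = n_add - nrow(ped),
       pe_ids = pe_ids, pe_sex = pe_sex, records = records,
       hys_levels = levels(hys), fixed_names = colnames(X),
       ped_animals = ped$animal,
       birth_date = ped$birth_date, sex = ped$sex, nrec = nrec)
}

# Jacobi-preconditioned conjugate gradients for the (positive-definite)
# mixed-model equations; relative residual 1e-10
cg_solve <- function(M, b, tol = 1e-12, max_iter = 20000L) {
  dinv <- 1 / Matrix::diag(M)
  x <- numeric(length(b))
  r <- b
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  bn <- sqrt(sum(b^2))
  for (i in seq_len(max_iter)) {
    Mp <- as.numeric(M %*% p)
    alpha <- rz / sum(p * Mp)
    x <- x + alpha * p
    r <- r - alpha * Mp
    if (sqrt(sum(r^2)) <= tol * bn) return(x)
    z <- dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  warning("conjugate gradients stopped at max_iter before reaching tolerance")
  x
}

# per-level PE variance-ratio vector lambda_p = sigma2_e_ref / sigma2_p(sex)
pe_lambda <- function(sys, vc) {
  s2p <- vc$sigma2_p
  if (length(s2p) == 1L && is.null(names(s2p))) {
    rep(vc$sigma2_e / s2p, length(sys$pe_ids))
  } else {
    unname(vc$sigma2_e / s2p[sys$pe_sex])
  }
}

# assemble coefficient matrix and right-hand side on the lambda scale
# (everything divided by the reference residual variance)
mme_matrix <- function(sys, vc, weights = NULL) {
  w <- if (is.null(weights)) rep(1, sys$nrec) else weights
  if (any(w <= 0)) stop("record weights must be positive")
  X <- sys$X; Za <- sys$Za; Zp <- sys$Zp
  W <- Matrix::Diagonal(x = w)
  XtW <- Matrix::t(X) %*% W
  ZatW <- Matrix::t(Za) %*% W
  ZptW <- Matrix::t(Zp) %*% W
  lam_a <- vc$sigma2_e / vc$sigma2_a
  lam_p <- pe_lambda(sys, vc)
  M <- rbind(
    cbind(XtW %*% X,  XtW %*% Za,  XtW %*% Zp),
    cbind(ZatW %*% X, ZatW %*% Za + lam_a * sys$ainv, ZatW %*% Zp),
    cbind(ZptW %*% X, ZptW %*% Za, ZptW %*% Zp + Matrix::Diagonal(x = lam_p)))
  rhs <- rbind(XtW %*% sys$y, ZatW %*% sys$y, ZptW %*% sys$y)
  list(M = Matrix::forceSymmetric(M), rhs = as.numeric(rhs), w = w,
       p = ncol(X), qa = ncol(Za), qp = ncol(Zp))
}

#' Solve the mixed-model equations
#'
#' Sparse LDL' factorization of the coefficient matrix; prediction-error
#' variances of breeding values are read from the additive-block diagonal of
#' the system inverse via the Takahashi selected-inversion recursion, so
#' they are exact, not approximated.
#'
#' @param sys system from [mme_system()].
#' @param vc variance components: list/[new_vc()] with `sigma2_a`,
#'   `sigma2_p` (scalar or named `c(M=, F=)`), `sigma2_e` (reference
#'   residual variance, the scale of weighted records).
#' @param weights optional per-record weights `sigma2_e_ref / sigma2_e(record)`
#'   realizing heterogeneous residual variances (default all 1).
#' @param pev compute prediction-error variances and reliabilities
#'   (direct method only; the iterative path flags them as not computed).
#' @param method `"direct"` (sparse LDL', the default) or `"cg"`
#'   (Jacobi-preconditioned conjugate gradients to relative residual
#'   1e-10, for systems too large to factor).
#' @return List of class `calf_mme_solution`: `ebv` (data frame with
#'   `animal`, `sex`, `birth_date`, `ebv`, `pev`, `reliability`, `ta`),
#'   `fixed`, `groups`, `pe`, plus fit diagnostics.
#' @export
solve_mme <- function(sys, vc, weights = NULL, pev = TRUE,
                      method = c("direct", "cg")) {
  method <- match.arg(method)
  mm <- mme_matrix(sys, vc, weights)
  if (method == "cg") {
    sol <- cg_solve(mm$M, mm$rhs)
    if (pev) message("prediction-error variances not computed on the iterative path")
    pev <- FALSE
  } else {
    fac <- sparse_factor(mm$M)
    sol <- as.numeric(sf_solve(fac, mm$rhs))
  }
  p <- mm$p; qa <- mm$qa
  fixed <- data.frame(effect = sys$fixed_names, estimate = sol[seq_len(p)],
                      stringsAsFactors = FALSE)
  uhat <- sol[p + seq_len(qa)]
  phat <- sol[p + qa + seq_len(mm$qp)]
  n_an <- sys$n_animals
  grp <- if (sys$n_groups > 0)
    data.frame(group = sys$add_ids[(n_an + 1):qa],
               estimate = uhat[(n_an + 1):qa], stringsAsFactors = FALSE)
  else data.frame(group = character(0), estimate = numeric(0))
  pev_v <- rel <- rep(NA_real_, n_an)
  if (pev && method == "direct") {
    fac <- sf_selected_inverse(fac)
    caa <- sf_inv_diag(fac, p + seq_len(n_an))
    pev_v <- caa * vc$sigma2_e
    rel <- pmin(pmax(1 - pev_v / (vc$sigma2_a * (1 + sys$f)), 0), 1)
  }
  ebv <- data.frame(animal = sys$add_ids[seq_len(n_an)],
                    sex = sys$sex, birth_date = sys$birth_date,
                    ebv = uhat[seq_len(n_an)], pev = pev_v, reliability = rel,
                    stringsAsFactors = FALSE)
  ebv$ta <- transmitting_ability(ebv$ebv)
  resid <- sys$y - as.numeric(sys$X %*% sol[seq_len(p)]) -
    as.numeric(sys$Za %*% uhat) - as.numeric(sys$Zp %*% phat)
  structure(list(ebv = ebv, fixed = fixed, groups = grp,
                 pe = data.frame(animal = sys$pe_ids, pe = phat,
                                 stringsAsFactors = FALSE),
                 residuals = resid, vc = vc, base = NULL),
            class = "calf_mme_solution")
}
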
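# Brute-force oracles shared across test files.

# O(N^2 M) dominance check (minimization); optional feasibility-first
# constraint domination mirroring the contract of the fast sort
brute_dominates <- function(a, b, va = 0, vb = 0) {
  if (va == 0 && vb > 0) return(TRUE)
  if (va > 0 && vb == 0) return(FALSE)
  if (va > 0 && vb > 0) return(va < vb)
  all(a <= b) && any(a < b)
}

# brute-force front ranks by repeated peeling
brute_nds <- function(objs, viol = NULL) {
  n <- nrow(objs)
  if (is.null(viol)) viol <- numeric(n)
  dom <- matrix(FALSE, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j)
        dom[i, j] <- brute_dominates(objs[i, ], objs[j, ], viol[i], viol[j])
  ranks <- integer(n)
  left <- rep(TRUE, n)
  r <- 0L
  while (any(left)) {
    r <- r + 1L
    idx <- which(left)
    fr <- idx[vapply(idx, function(j) !any(dom[idx, j]), logical(1))]
    ranks[fr] <- r
    left[fr] <- FALSE
  }
  ranks
}

# straightforward IGD
brute_igd <- function(P, Q) {
  mean(apply(P, 1, function(p)
    sqrt(min(colSums((t(Q) - p)^2)))))
}

# independent scalar (loop-based) benchmark objective implementations
ref_problem <- function(name, x) {
  D <- length(x)
  switch(name,
    ZDT1 = {
      g <- 1 + 9 * sum(x[-1]) / (D - 1)
      c(x[1], g * (1 - sqrt(x[1] / g)))
    },
    ZDT2 = {
      g <- 1 + 9 * sum(x[-1]) / (D - 1)
      c(x[1], g * (1 - (x[1] / g)^2))
    },
    ZDT3 = {
      g <- 1 + 9 * sum(x[-1]) / (D - 1)
      c(x[1], g * (1 - sqrt(x[1] / g) - x[1] / g * sin(10 * pi * x[1])))
    },
    UF1 = {
      s1 <- 0; n1 <- 0; s2 <- 0; n2 <- 0
      for (j in 2:D) {
        y <- x[j] - sin(6 * pi * x[1] + j * pi / D)
        if (j %% 2 == 1) { s1 <- s1 + y^2; n1 <- n1 + 1 }
        else { s2 <- s2 + y^2; n2 <- n2 + 1 }
      }
      c(x[1] + 2 / n1 * s1, 1 - sqrt(x[1]) + 2 / n2 * s2)
    },
    UF2 = {
      s1 <- 0; n1 <- 0; s2 <- 0; n2 <- 0
      for (j in 2:D) {
        if (j %% 2 == 1) {
          y <- x[j] - (0.3 * x[1]^2 * cos(24 * pi * x[1] + 4 * j * pi / D) +
                         0.6 * x[1]) * cos(6 * pi * x[1] + j * pi / D)
          s1 <- s1 + y^2; n1 <- n1 + 1
        } else {
          y <- x[j] - (0.3 * x[1]^2 * cos(24 * pi * x[1] + 4 * j * pi / D) +
                         0.6 * x[1]) * sin(6 * pi * x[1] + j * pi / D)
          s2 <- s2 + y^2; n2 <- n2 + 1
        }
      }
      c(x[1] + 2 / n1 * s1, 1 - sqrt(x[1]) + 2 / n2 * s2)
    },
    UF3 = {
      s1 <- 0; p1 <- 1; n1 <- 0; s2 <- 0; p2 <- 1; n2 <- 0
      for (j in 2:D) {
        y <- x[j] - x[1]^(0.5 * (1 + 3 * (j - 2) / (D - 2)))
        if (j %% 2 == 1) {
          s1 <- s1 + y^2; p1 <- p1 * cos(20 * y * pi / sqrt(j)); n1 <- n1 + 1
        } else {
          s2 <- s2 + y^2; p2 <- p2 * cos(20 * y * pi / sqrt(j)); n2 <- n2 + 1
        }
      }
      c(x[1] + 2 / n1 * (4 * s1 - 2 * p1 + 2),
        1 - sqrt(x[1]) + 2 / n2 * (4 * s2 - 2 * p2 + 2))
    },
    DTLZ1 = {
      M <- 3; k <- D - M + 1
      xm <- x[M:D]
      g <- 100 * (k + sum((xm - 0.5)^2 - cos(20 * pi * (xm - 0.5))))
      f <- numeric(M)
      for (m in 1:M) {
        v <- 0.5 * (1 + g)
        if (M - m >= 1) for (j in 1:(M - m)) v <- v * x[j]
        if (m > 1) v <- v * (1 - x[M - m + 1])
        f[m] <- v
      }
      f
    },
    DTLZ2 = ,
    DTLZ3 = {
      M <- 3; k <- D - M + 1
      xm <- x[M:D]
      g <- if (name == "DTLZ2") sum((xm - 0.5)^2)
           else 100 * (k + sum((xm - 0.5)^2 - cos(20 * pi * (xm - 0.5))))
      f <- numeric(M)
      for (m in 1:M) {
        v <- 1 + g
        if (M - m >= 1) for (j in 1:(M - m)) v <- v * cos(x[j] * pi / 2)
        if (m > 1) v <- v * sin(x[M - m + 1] * pi / 2)
        f[m] <- v
      }
      f
    },
    DTLZ7 = {
      M <- 3; k <- D - M + 1
      g <- 1 + 9 / k * sum(x[M:D])
      f <- c(x[1], x[2], 0)
      h <- M - sum(f[1:(M - 1)] / (1 + g) * (1 + sin(3 * pi * f[1:(M - 1)])))
      f[M] <- (1 + g) * h
      f
    },
    stop("unknown problem ", name))
}

# small demonstration influent used by CSTR calibration tests
test_cstr_influent <- function() {
  asm2d_state(SO2 = 2, SF = 60, SA = 40, SNH4 = 25, SPO4 = 8, SALK = 5,
              SI = 30, XI = 50, XS = 120, XH = 30, XPAO = 10, XPP = 2,
              XPHA = 1, XAUT = 2, SNO3 = 0.5)
}
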
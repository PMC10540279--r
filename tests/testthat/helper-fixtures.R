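# shared fixture builders -- everything is generated in code

# flat trigonal complex: Pd at (0,0,offset), P + two C donors in z = 0
flatComplex <- function(offset = 0, ligand = "L1", role = "pro_S") {
  xyzStructure(c("Pd", "P", "C", "C"),
               rbind(c(0, 0, offset), c(2, 0, 0),
                     c(-1, 1.7, 0), c(-1, -1.7, 0)),
               ligandId = ligand, role = role)
}

stdDonors <- function() donorSet(metal = 1, donors = 2:4, p = 2)

# apply a random (seeded) rigid motion to a structure
rigidMotion <- function(s, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- runif(3, -10, 10)
  xyzStructure(elements(s), sweep(coords(s) %*% t(q), 2, shift, "+"),
               ligandId = s@ligandId, role = s@role)
}

# small labeled table with known values
tinyTable <- function() {
  m <- cbind(a = c(2, 4, 6, 8), b = c(1, 1, 2, 4), const = c(5, 5, 5, 5))
  rownames(m) <- sprintf("L%d", 1:4)
  featureTable(m, provenance = c("geometric", "electronic", "other"),
               labels = selectivity(s = c(60, 70, 80, 90)))
}
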
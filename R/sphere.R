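## Spherical geometry helpers shared across modules.
## Convention: latitude phi measured from the equator (phi = asin(z)),
## longitude lambda = atan2(y, x).

.unitize <- function(m) {
    m <- as.matrix(m)
    m / sqrt(rowSums(m^2))
}

.cartToLatLon <- function(v) {
    v <- as.matrix(v)
    cbind(phi = asin(pmin(1, pmax(-1, v[, 3]))),
          lambda = atan2(v[, 2], v[, 1]))
}

.latLonToCart <- function(phi, lambda) {
    cbind(cos(phi) * cos(lambda), cos(phi) * sin(lambda), sin(phi))
}

## angle between axes (antipodally symmetric), degrees
.axisAngleDeg <- function(a, b) {
    acos(pmin(1, abs(drop(a %*% b)))) * 180 / pi
}

## Rodrigues rotation taking unit vector 'from' to unit vector 'to'
.rotationBetween <- function(from, to) {
    v <- c(from[2] * to[3] - from[3] * to[2],
           from[3] * to[1] - from[1] * to[3],
           from[1] * to[2] - from[2] * to[1])
    c_ <- sum(from * to)
    s <- sqrt(sum(v^2))
    if (s < 1e-14) {
        if (c_ > 0) return(diag(3))
        ## antipodal: rotate by pi about any axis orthogonal to 'from'
        a <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        axis <- a - sum(a * from) * from
        axis <- axis / sqrt(sum(axis^2))
        return(2 * tcrossprod(axis) - diag(3))
    }
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

## random rotation matrix (QR of Gaussian, determinant fixed to +1)
.randomRotation <- function() {
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
}

## ---------------------------------------------------------------------------
## Icosphere tessellation (used for ODF peak search)
## ---------------------------------------------------------------------------

.icosahedron <- function() {
    t <- (1 + sqrt(5)) / 2
    v <- rbind(
        c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
        c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
        c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
    f <- rbind(
        c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
        c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
        c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
        c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
    list(vertices = .unitize(v), faces = f)
}

## Subdivide each face into 4; deduplicate shared edge midpoints.
.icosphere <- function(subdiv = 3L) {
    mesh <- .icosahedron()
    for (s in seq_len(subdiv)) {
        v <- mesh$vertices
        f <- mesh$faces
        key <- function(i, j) paste(pmin(i, j), pmax(i, j))
        cache <- new.env(hash = TRUE, parent = emptyenv())
        verts <- v
        midpoint <- function(i, j) {
            k <- key(i, j)
            idx <- cache[[k]]
            if (is.null(idx)) {
                p <- verts[i, ] + verts[j, ]
                p <- p / sqrt(sum(p^2))
                verts <<- rbind(verts, p)
                idx <- nrow(verts)
                cache[[k]] <- idx
            }
            idx
        }
        nf <- matrix(0L, 4L * nrow(f), 3L)
        for (i in seq_len(nrow(f))) {
            a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
            ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
            nf[4L * i - 3L, ] <- c(a, ab, ca)
            nf[4L * i - 2L, ] <- c(b, bc, ab)
            nf[4L * i - 1L, ] <- c(c_, ca, bc)
            nf[4L * i, ] <- c(ab, bc, ca)
        }
        mesh <- list(vertices = verts, faces = nf)
    }
    mesh
}

## package-local cache (tessellations, vertex adjacency)
.dmriCache <- new.env(parent = emptyenv())

## Hemisphere tessellation with vertex neighbour lists, cached by subdivision
## level. Vertices with z > -1e-9 are kept (equator retained once via the
## z >= 0 rule with x/y tie-breaks).
.hemisphereTessellation <- function(subdiv = 3L) {
    keyname <- paste0("hemi", subdiv)
    got <- .dmriCache[[keyname]]
    if (!is.null(got)) return(got)
    mesh <- .icosphere(subdiv)
    v <- mesh$vertices
    keep <- v[, 3] > 1e-9 |
        (abs(v[, 3]) <= 1e-9 & (v[, 2] > 1e-9 |
            (abs(v[, 2]) <= 1e-9 & v[, 1] > 0)))
    idx <- which(keep)
    map <- integer(nrow(v))
    map[idx] <- seq_along(idx)
    verts <- v[idx, , drop = FALSE]
    ## adjacency on the axes: from faces, mapping dropped vertices to their
    ## antipodes among the kept ones
    anti <- integer(nrow(v))
    for (i in which(!keep)) {
        d <- rowSums((verts + matrix(v[i, ], nrow(verts), 3,
            byrow = TRUE))^2)
        anti[i] <- which.min(d)
    }
    vid <- ifelse(keep, map, anti)
    nb <- vector("list", nrow(verts))
    f <- mesh$faces
    edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    e1 <- vid[edges[, 1]]; e2 <- vid[edges[, 2]]
    ok <- e1 != e2
    e1 <- e1[ok]; e2 <- e2[ok]
    nb <- split(c(e2, e1), c(e1, e2))
    neighbours <- lapply(seq_len(nrow(verts)), function(i) {
        x <- nb[[as.character(i)]]
        sort(unique(x))
    })
    out <- list(vertices = verts, neighbours = neighbours)
    .dmriCache[[keyname]] <- out
    out
}
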
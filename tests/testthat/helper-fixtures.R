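# Shared fixtures, built in code. Heavy objects are cached per test run.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_env, inherits = FALSE)) {
    assign(name, force(expr), envir = fixture_env)
  }
  get(name, envir = fixture_env, inherits = FALSE)
}

# coarse phantom for unit tests
small_phantom <- function() cached("small_phantom", femur_phantom(1, 42))

# study-resolution phantom (the default study conditions)
study_phantom_c3 <- function() cached("study_phantom_c3", femur_phantom(3, 101))

# regular tetrahedron over (0,0,0),(1,0,0),(0,1,0),(0,0,1), outward winding
unit_tetra <- function() {
  tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
}

# closed cylinder (axis z) with 2*segments side triangles and fan caps;
# 4*segments triangles total - used where an exact triangle-count ratio
# between two watertight meshes is needed
mesh_cylinder <- function(radius = 10, height = 20, segments = 32) {
  th <- seq(0, 2 * pi, length.out = segments + 1)[-(segments + 1)]
  ring_lo <- cbind(radius * cos(th), radius * sin(th), 0)
  ring_hi <- cbind(radius * cos(th), radius * sin(th), height)
  v <- rbind(ring_lo, ring_hi, c(0, 0, 0), c(0, 0, height))
  lo <- seq_len(segments)
  hi <- segments + lo
  nxt <- c(lo[-1], lo[1])
  c_lo <- 2 * segments + 1
  c_hi <- 2 * segments + 2
  f <- rbind(
    cbind(lo, nxt, segments + nxt),       # side lower
    cbind(lo, segments + nxt, hi),        # side upper
    cbind(c_lo, nxt, lo),                 # bottom cap (faces -z)
    cbind(c_hi, hi, segments + nxt)       # top cap (faces +z)
  )
  tri_mesh(v, f)
}

# random rotation matrix with angle <= max_angle (radians)
random_rotation <- function(max_angle) {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  a <- runif(1, 0, max_angle)
  k <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  diag(3) + sin(a) * k + (1 - cos(a)) * k %*% k
}

# default-conditions study outputs, computed once and shared by the
# acceptance tests
default_sege_sweep <- function() {
  cached("default_sege_sweep", run_sege_sweep(study_config()))
}
default_dee_study <- function() {
  cached("default_dee_study", run_dee_study(study_config()))
}
default_pre_study <- function() {
  cached("default_pre_study", run_pre_study(study_config()))
}
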
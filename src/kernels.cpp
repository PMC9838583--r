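#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen thinning of a binary image. Input/output: 0/1 integer matrix.
// Produces a one-pixel-wide 8-connected skeleton.
// [[Rcpp::export(name = ".cpp_thin")]]
IntegerMatrix cpp_thin(IntegerMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix m(clone(img));
  std::vector<std::pair<int,int> > kill;
  bool changed = true;
  // neighbours P2..P9 clockwise starting north (row-1,col)
  const int dr[8] = {-1,-1, 0, 1, 1, 1, 0,-1};
  const int dc[8] = { 0, 1, 1, 1, 0,-1,-1,-1};
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int i = 1; i < nr - 1; ++i) {
        for (int j = 1; j < nc - 1; ++j) {
          if (!m(i, j)) continue;
          int p[8];
          for (int k = 0; k < 8; ++k) p[k] = m(i + dr[k], j + dc[k]);
          int B = 0, A = 0;
          for (int k = 0; k < 8; ++k) {
            B += p[k];
            if (!p[k] && p[(k + 1) % 8]) ++A;
          }
          if (B < 2 || B > 6 || A != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k) m(kill[k].first, kill[k].second) = 0;
    }
  }
  return m;
}

// Stamp filled disks onto a canvas; used by the rasterizer. rows/cols are
// 1-based pixel-centre coordinates (double), radius in px. val is written
// where the disk covers a pixel centre.
// [[Rcpp::export(name = ".cpp_stamp_disks")]]
void cpp_stamp_disks(IntegerMatrix canvas, NumericVector row, NumericVector col,
                     NumericVector radius, int val) {
  int nr = canvas.nrow(), nc = canvas.ncol();
  int n = row.size();
  for (int k = 0; k < n; ++k) {
    double r0 = row[k], c0 = col[k], rad = radius[k];
    if (rad < 0) continue;
    double r2 = rad * rad;
    int ilo = std::max(0, (int)std::floor(r0 - rad) - 1);
    int ihi = std::min(nr - 1, (int)std::ceil(r0 + rad));
    int jlo = std::max(0, (int)std::floor(c0 - rad) - 1);
    int jhi = std::min(nc - 1, (int)std::ceil(c0 + rad));
    for (int i = ilo; i <= ihi; ++i) {
      double dy = (i + 1) - r0;
      for (int j = jlo; j <= jhi; ++j) {
        double dx = (j + 1) - c0;
        if (dy * dy + dx * dx <= r2) canvas(i, j) = val;
      }
    }
  }
}

// Sandbox mass counts: for each centre, count structure pixels within each
// radius (Euclidean, pixel centres). Returns a (n_centers x n_radii) matrix.
// [[Rcpp::export(name = ".cpp_sandbox_counts")]]
IntegerMatrix cpp_sandbox_counts(IntegerVector px_row, IntegerVector px_col,
                                 NumericVector ctr_row, NumericVector ctr_col,
                                 NumericVector radii) {
  int np = px_row.size(), ncen = ctr_row.size(), nrad = radii.size();
  std::vector<double> r2(nrad);
  for (int r = 0; r < nrad; ++r) r2[r] = radii[r] * radii[r];
  IntegerMatrix out(ncen, nrad);
  for (int c = 0; c < ncen; ++c) {
    std::vector<int> hist(nrad + 1, 0);
    double cr = ctr_row[c], cc = ctr_col[c];
    double rmax2 = r2[nrad - 1];
    for (int p = 0; p < np; ++p) {
      double dy = px_row[p] - cr, dx = px_col[p] - cc;
      double d2 = dy * dy + dx * dx;
      if (d2 > rmax2) continue;
      // first radius index with r2 >= d2
      int lo = 0, hi = nrad - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (r2[mid] >= d2) hi = mid; else lo = mid + 1;
      }
      hist[lo] += 1;
    }
    int cum = 0;
    for (int r = 0; r < nrad; ++r) {
      cum += hist[r];
      out(c, r) = cum;
    }
  }
  return out;
}

// 8-neighbour count of foreground pixels, for skeleton graph topology.
// [[Rcpp::export(name = ".cpp_neighbor_count")]]
IntegerMatrix cpp_neighbor_count(IntegerMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      if (!m(i, j)) continue;
      int s = 0;
      for (int di = -1; di <= 1; ++di)
        for (int dj = -1; dj <= 1; ++dj) {
          if (!di && !dj) continue;
          int ii = i + di, jj = j + dj;
          if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
          s += m(ii, jj) ? 1 : 0;
        }
      out(i, j) = s;
    }
  return out;
}

// Trace ordered pixel chains between node pixels on a 1-px skeleton.
// node_id > 0 marks node-cluster pixels. Chains start at a node pixel,
// walk through non-node pixels (orthogonal neighbours preferred so
// staircase corners are walked through), and end at a node pixel or a
// dangling end. Returns parallel lists: from, to (0 = none), and the
// chain pixel coordinates (1-based, row/col interleaved).
// [[Rcpp::export(name = ".cpp_trace_chains")]]
List cpp_trace_chains(IntegerMatrix skel, IntegerMatrix node_id) {
  int nr = skel.nrow(), nc = skel.ncol();
  const int dr[8] = {-1, 0, 1, 0, -1, 1, 1, -1};
  const int dc[8] = {0, 1, 0, -1, 1, 1, -1, -1};
  std::vector<char> visited((size_t)nr * nc, 0);
  std::vector<int> from_v, to_v;
  std::vector< std::vector<int> > chains;
  for (int j0 = 0; j0 < nc; ++j0) for (int i0 = 0; i0 < nr; ++i0) {
    if (node_id(i0, j0) <= 0) continue;
    int ni = node_id(i0, j0);
    for (int k = 0; k < 8; ++k) {
      int i1 = i0 + dr[k], j1 = j0 + dc[k];
      if (i1 < 0 || j1 < 0 || i1 >= nr || j1 >= nc) continue;
      if (!skel(i1, j1) || node_id(i1, j1) > 0) continue;
      if (visited[(size_t)i1 * nc + j1]) continue;
      std::vector<int> chain;
      chain.push_back(i0 + 1); chain.push_back(j0 + 1);
      chain.push_back(i1 + 1); chain.push_back(j1 + 1);
      visited[(size_t)i1 * nc + j1] = 1;
      int pr = i0, pc = j0, cr = i1, cc = j1;
      int to = 0;
      while (true) {
        int nr2 = -1, nc2 = -1, is_node = 0;
        for (int m = 0; m < 8; ++m) {
          int rr = cr + dr[m], c2 = cc + dc[m];
          if (rr < 0 || c2 < 0 || rr >= nr || c2 >= nc) continue;
          if (!skel(rr, c2)) continue;
          if (rr == pr && c2 == pc) continue;
          if (node_id(rr, c2) > 0) {
            if (node_id(rr, c2) == ni && chain.size() == 4) continue;
            nr2 = rr; nc2 = c2; is_node = 1; break;
          }
          if (!visited[(size_t)rr * nc + c2] && nr2 < 0) { nr2 = rr; nc2 = c2; }
        }
        if (nr2 < 0) { to = 0; break; }   // dangling end
        chain.push_back(nr2 + 1); chain.push_back(nc2 + 1);
        if (is_node) { to = node_id(nr2, nc2); break; }
        visited[(size_t)nr2 * nc + nc2] = 1;
        pr = cr; pc = cc; cr = nr2; cc = nc2;
      }
      from_v.push_back(ni); to_v.push_back(to);
      chains.push_back(chain);
    }
  }
  List ch_out(chains.size());
  for (size_t i = 0; i < chains.size(); ++i) {
    int n = chains[i].size() / 2;
    IntegerMatrix m(n, 2);
    for (int p = 0; p < n; ++p) {
      m(p, 0) = chains[i][2 * p];
      m(p, 1) = chains[i][2 * p + 1];
    }
    ch_out[i] = m;
  }
  return List::create(Named("from") = wrap(from_v),
                      Named("to") = wrap(to_v),
                      Named("chains") = ch_out);
}

// 8-connected component labeling of a binary matrix (node clusters).
// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(LogicalMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lbl(nr, nc);
  const int dr[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1,-1, 1,-1, 0, 1};
  int cur = 0;
  std::vector< std::pair<int,int> > stack;
  for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
    if (!m(i, j) || lbl(i, j)) continue;
    ++cur;
    stack.clear();
    stack.push_back(std::make_pair(i, j));
    lbl(i, j) = cur;
    while (!stack.empty()) {
      std::pair<int,int> p = stack.back(); stack.pop_back();
      for (int k = 0; k < 8; ++k) {
        int r = p.first + dr[k], c = p.second + dc[k];
        if (r < 0 || c < 0 || r >= nr || c >= nc) continue;
        if (m(r, c) && !lbl(r, c)) {
          lbl(r, c) = cur;
          stack.push_back(std::make_pair(r, c));
        }
      }
    }
  }
  return lbl;
}
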
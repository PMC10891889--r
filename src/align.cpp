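// Linear-space global affine-gap alignment (Myers & Miller style
// divide-and-conquer) for whole-genome nucleotide identity.
//
// Scoring: match / mismatch substitution scores; a gap of length k
// costs gapOpen + k * gapExtend (end gaps penalized).  The algorithm
// minimizes cost = -score.  Besides the optimal score it returns the
// number of identical aligned columns and the total alignment length
// of one optimal alignment, from which percent identity is derived.

#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

namespace {

const double INF = 1e18;

struct Aligner {
  const std::string &A, &B;
  double mat, mis, g, h;
  long long matches = 0, columns = 0;
  double topCost = 0.0;
  bool haveTop = false;

  Aligner(const std::string& a, const std::string& b, double mat_,
          double mis_, double g_, double h_)
      : A(a), B(b), mat(mat_), mis(mis_), g(g_), h(h_) {}

  static bool isBase(char x) {
    return x == 'A' || x == 'C' || x == 'G' || x == 'T';
  }
  bool eq(char x, char y) const { return x == y && isBase(x); }
  double w(char x, char y) const { return eq(x, y) ? -mat : -mis; }

  // forward pass over A[ia..ia+M-1] x B[ib..ib+N-1]; on exit CC[j] is
  // the best cost to (M, j) and DD[j] the best cost to (M, j) ending
  // in a deletion (vertical gap), with top-boundary deletion open tb
  // applying at column 0.
  void forward(int ia, int M, int ib, int N, double tb,
               std::vector<double>& CC, std::vector<double>& DD) {
    CC[0] = 0.0;
    double t = g;
    for (int j = 1; j <= N; ++j) {
      t += h;
      CC[j] = t;
      DD[j] = t + g;
    }
    t = tb;
    for (int i = 1; i <= M; ++i) {
      double s = CC[0];
      t += h;
      double c = t;
      CC[0] = c;
      double e = t + g;
      for (int j = 1; j <= N; ++j) {
        e = std::min(e, c + g) + h;
        DD[j] = std::min(DD[j], CC[j] + g) + h;
        c = std::min(std::min(DD[j], e),
                     s + w(A[ia + i - 1], B[ib + j - 1]));
        s = CC[j];
        CC[j] = c;
      }
    }
    DD[0] = (M > 0) ? tb + h * M : INF;
  }

  // mirror image of forward() on the reversed segments; RR[j] is the
  // best cost of aligning the whole A segment with B columns (j..N],
  // SS[j] additionally requires the alignment to start with a
  // deletion (open charged; bottom-boundary open te at column N).
  void backward(int ia, int M, int ib, int N, double te,
                std::vector<double>& RR, std::vector<double>& SS) {
    std::string ar(A.rbegin() + (A.size() - (ia + M)), A.rbegin() + (A.size() - ia));
    std::string br(B.rbegin() + (B.size() - (ib + N)), B.rbegin() + (B.size() - ib));
    std::vector<double> CC(N + 1), DD(N + 1);
    Aligner rev(ar, br, mat, mis, g, h);
    rev.forward(0, M, 0, N, te, CC, DD);
    for (int j = 0; j <= N; ++j) {
      RR[j] = CC[N - j];
      SS[j] = DD[N - j];
    }
  }

  void setTop(double cost, bool top) {
    if (top && !haveTop) {
      topCost = cost;
      haveTop = true;
    }
  }

  void diff(int ia, int M, int ib, int N, double tb, double te, bool top) {
    if (N == 0) {
      setTop(M > 0 ? std::min(tb, te) + h * M : 0.0, top);
      columns += M;
      return;
    }
    if (M == 0) {
      setTop(g + h * N, top);
      columns += N;
      return;
    }
    if (M == 1) {
      char a1 = A[ia];
      double best = std::min(tb, te) + h + g + h * N;
      int bestj = -1;
      for (int j = 1; j <= N; ++j) {
        double c = w(a1, B[ib + j - 1]);
        if (j > 1) c += g + h * (j - 1);
        if (j < N) c += g + h * (N - j);
        if (c < best - 1e-12) {
          best = c;
          bestj = j;
        }
      }
      setTop(best, top);
      if (bestj < 0) {
        columns += 1 + N;
      } else {
        columns += N;
        if (eq(a1, B[ib + bestj - 1])) ++matches;
      }
      return;
    }
    if (N == 1) {
      char b1 = B[ib];
      double best = std::min(tb, te) + h * M + g + h;
      int besti = -1;
      for (int i = 1; i <= M; ++i) {
        double c = w(A[ia + i - 1], b1);
        if (i > 1) c += tb + h * (i - 1);
        if (i < M) c += te + h * (M - i);
        if (c < best - 1e-12) {
          best = c;
          besti = i;
        }
      }
      setTop(best, top);
      if (besti < 0) {
        columns += M + 1;
      } else {
        columns += M;
        if (eq(A[ia + besti - 1], b1)) ++matches;
      }
      return;
    }

    int i0 = M / 2;
    std::vector<double> CC(N + 1), DD(N + 1), RR(N + 1), SS(N + 1);
    forward(ia, i0, ib, N, tb, CC, DD);
    backward(ia + i0, M - i0, ib, N, te, RR, SS);
    double best = INF;
    int bestj = 0, type = 1;
    for (int j = 0; j <= N; ++j) {
      double c1 = CC[j] + RR[j];
      if (c1 < best) {
        best = c1;
        bestj = j;
        type = 1;
      }
    }
    for (int j = 0; j <= N; ++j) {
      double c2 = DD[j] + SS[j] - g;
      if (c2 < best) {
        best = c2;
        bestj = j;
        type = 2;
      }
    }
    setTop(best, top);
    if (type == 1) {
      diff(ia, i0, ib, bestj, tb, g, false);
      diff(ia + i0, M - i0, ib + bestj, N - bestj, g, te, false);
    } else {
      diff(ia, i0 - 1, ib, bestj, tb, 0.0, false);
      columns += 2;  // a[i0] and a[i0+1] deleted across the midline
      diff(ia + i0 + 1, M - i0 - 1, ib + bestj, N - bestj, 0.0, te, false);
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".mmAlign")]]
Rcpp::List mmAlign(std::string a, std::string b, double match,
                   double mismatch, double gapOpen, double gapExtend) {
  Aligner al(a, b, match, mismatch, gapOpen, gapExtend);
  al.diff(0, (int)a.size(), 0, (int)b.size(), gapOpen, gapOpen, true);
  double score = -al.topCost;
  double identity =
      al.columns > 0 ? 100.0 * (double)al.matches / (double)al.columns : 0.0;
  return Rcpp::List::create(
      Rcpp::Named("score") = score, Rcpp::Named("matches") = (double)al.matches,
      Rcpp::Named("columns") = (double)al.columns,
      Rcpp::Named("identity") = identity);
}
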
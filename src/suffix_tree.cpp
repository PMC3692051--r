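// Generalized suffix tree over an integer-encoded concatenation of the input
// sequences, one unique terminator symbol per sequence, built with Ukkonen's
// online algorithm (O(M) amortized; a work counter backs the linearity
// contract empirically). Enumeration walks the tree once per k and reports
// every depth-k locus whose first k symbols are plain alphabet letters,
// together with all occurrence positions read off the leaves below it.

#include <Rcpp.h>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct STNode {
  std::map<int, int> next;
  int start;  // edge label = text[start, end)
  int end;    // -1 while open (leaf during construction)
  int link;
  STNode(int s, int e) : start(s), end(e), link(0) {}
};

struct GSTIndex {
  std::vector<int> text;
  std::vector<STNode> nodes;
  int n_core;     // symbols < n_core may appear in reported words
  int n_letters;  // core + ambiguity; symbols >= n_letters are terminators
  std::vector<int> seq_start;  // global start of each sequence (0-based)
  std::vector<int> seq_of;     // sequence index (0-based) per text position
  long long work;
  int M;
  int n_leaves;
  std::vector<int> parent, node_depth, leaf_lo, leaf_hi;
  std::vector<int> leaf_suffix;  // global suffix start per leaf slot
  std::vector<int> preorder;
};

class Builder {
 public:
  GSTIndex* g;
  int activeNode, activeEdge, activeLen, remainder, needSL, pos;

  explicit Builder(GSTIndex* gi)
      : g(gi), activeNode(0), activeEdge(0), activeLen(0), remainder(0),
        needSL(0), pos(-1) {
    g->nodes.reserve(2 * g->text.size() + 4);
    g->nodes.push_back(STNode(-1, -1));  // root
    g->work = 0;
  }

  int new_node(int s, int e) {
    g->nodes.push_back(STNode(s, e));
    return (int)g->nodes.size() - 1;
  }

  int edge_length(int v) const {
    int e = g->nodes[v].end;
    return ((e == -1) ? pos + 1 : e) - g->nodes[v].start;
  }

  void add_sl(int node) {
    if (needSL > 0) g->nodes[needSL].link = node;
    needSL = node;
  }

  bool walk_down(int node) {
    int l = edge_length(node);
    if (activeLen >= l) {
      activeEdge += l;
      activeLen -= l;
      activeNode = node;
      return true;
    }
    return false;
  }

  void extend(int i) {
    pos = i;
    needSL = 0;
    ++remainder;
    const std::vector<int>& text = g->text;
    while (remainder > 0) {
      ++g->work;
      if (activeLen == 0) activeEdge = i;
      std::map<int, int>& nx = g->nodes[activeNode].next;
      std::map<int, int>::iterator it = nx.find(text[activeEdge]);
      if (it == nx.end()) {
        int leaf = new_node(i, -1);
        nx[text[activeEdge]] = leaf;
        add_sl(activeNode);
      } else {
        int nxt = it->second;
        if (walk_down(nxt)) continue;
        if (text[g->nodes[nxt].start + activeLen] == text[i]) {
          ++activeLen;
          add_sl(activeNode);
          break;
        }
        int split = new_node(g->nodes[nxt].start,
                             g->nodes[nxt].start + activeLen);
        g->nodes[activeNode].next[text[activeEdge]] = split;
        int leaf = new_node(i, -1);
        g->nodes[split].next[text[i]] = leaf;
        g->nodes[nxt].start += activeLen;
        g->nodes[split].next[text[g->nodes[nxt].start]] = nxt;
        add_sl(split);
      }
      --remainder;
      if (activeNode == 0 && activeLen > 0) {
        --activeLen;
        activeEdge = i - remainder + 1;
      } else {
        activeNode = g->nodes[activeNode].link;
      }
    }
  }

  void run() {
    int M = (int)g->text.size();
    for (int i = 0; i < M; ++i) extend(i);
  }
};

struct Frame {
  int v;
  std::map<int, int>::iterator it;
};

void finalize(GSTIndex& g) {
  int M = (int)g.text.size();
  g.M = M;
  int nn = (int)g.nodes.size();
  for (int v = 1; v < nn; ++v)
    if (g.nodes[v].end == -1) g.nodes[v].end = M;
  g.parent.assign(nn, -1);
  g.node_depth.assign(nn, 0);
  g.leaf_lo.assign(nn, 0);
  g.leaf_hi.assign(nn, 0);
  g.leaf_suffix.clear();
  g.preorder.clear();
  g.preorder.reserve(nn);
  std::vector<Frame> st;
  Frame f0;
  f0.v = 0;
  f0.it = g.nodes[0].next.begin();
  st.push_back(f0);
  while (!st.empty()) {
    Frame& f = st.back();
    int v = f.v;
    if (f.it == g.nodes[v].next.end()) {
      g.leaf_hi[v] = (int)g.leaf_suffix.size();
      st.pop_back();
      continue;
    }
    int u = f.it->second;
    ++f.it;
    g.parent[u] = v;
    g.node_depth[u] = g.node_depth[v] + (g.nodes[u].end - g.nodes[u].start);
    g.leaf_lo[u] = (int)g.leaf_suffix.size();
    g.preorder.push_back(u);
    if (g.nodes[u].next.empty()) {
      g.leaf_suffix.push_back(M - g.node_depth[u]);
      g.leaf_hi[u] = (int)g.leaf_suffix.size();
    } else {
      Frame fu;
      fu.v = u;
      fu.it = g.nodes[u].next.begin();
      st.push_back(fu);
    }
  }
  g.n_leaves = (int)g.leaf_suffix.size();
}

}  // namespace

// [[Rcpp::export(name = ".gst_build_cpp")]]
SEXP gst_build_cpp(IntegerVector text, int n_core, int n_letters,
                   IntegerVector seq_start, IntegerVector seq_len) {
  XPtr<GSTIndex> p(new GSTIndex(), true);
  p->text = as<std::vector<int> >(text);
  p->n_core = n_core;
  p->n_letters = n_letters;
  p->seq_start = as<std::vector<int> >(seq_start);
  int ns = seq_start.size();
  p->seq_of.assign(p->text.size(), 0);
  for (int s = 0; s < ns; ++s) {
    int from = seq_start[s];
    int to = (s + 1 < ns) ? seq_start[s + 1] : (int)p->text.size();
    for (int i = from; i < to; ++i) p->seq_of[i] = s;
  }
  Builder b(p);
  b.run();
  finalize(*p);
  return p;
}

// [[Rcpp::export(name = ".gst_stats_cpp")]]
List gst_stats_cpp(SEXP xp) {
  XPtr<GSTIndex> p(xp);
  return List::create(_["M"] = p->M, _["n_nodes"] = (int)p->nodes.size() - 1,
                      _["n_leaves"] = p->n_leaves,
                      _["work"] = (double)p->work);
}

// All distinct words of length k over the core alphabet, with every
// occurrence as (sequence, 0-based offset). Words come out in preorder,
// i.e. lexicographically when symbol codes follow letter order.
// [[Rcpp::export(name = ".gst_enumerate_cpp")]]
List gst_enumerate_cpp(SEXP xp, int k, CharacterVector letters) {
  XPtr<GSTIndex> p(xp);
  std::vector<std::string> words;
  std::vector<int> n_occ, occ_seq, occ_pos;
  std::string buf(k, ' ');
  for (size_t pi = 0; pi < p->preorder.size(); ++pi) {
    int u = p->preorder[pi];
    int pd = p->node_depth[p->parent[u]];
    int d = p->node_depth[u];
    if (!(pd < k && k <= d)) continue;
    int g0 = p->leaf_suffix[p->leaf_lo[u]];
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int sym = p->text[g0 + j];
      if (sym >= p->n_core) {
        ok = false;
        break;
      }
      buf[j] = CHAR(STRING_ELT(letters, sym))[0];
    }
    if (!ok) continue;
    words.push_back(buf);
    int cnt = 0;
    for (int li = p->leaf_lo[u]; li < p->leaf_hi[u]; ++li) {
      int g = p->leaf_suffix[li];
      int s = p->seq_of[g];
      occ_seq.push_back(s + 1);
      occ_pos.push_back(g - p->seq_start[s]);
      ++cnt;
    }
    n_occ.push_back(cnt);
  }
  return List::create(_["word"] = wrap(words), _["n_occ"] = wrap(n_occ),
                      _["occ_seq"] = wrap(occ_seq),
                      _["occ_pos"] = wrap(occ_pos));
}
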
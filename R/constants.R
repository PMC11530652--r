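# Internal lexicons for the synthetic dialogue generator and the oracle
# predictor's decoys. The noun list is deliberately concentrated on a dozen
# initial letters so that several vocabulary words share each initial: that is
# what makes initials-only expansion genuinely ambiguous and gives
# conversational context something to disambiguate.

.abbrex_nouns <- c(
  "bedroom", "backyard", "beach", "bakery", "banjo", "basement", "bicycle",
  "birthday", "blanket", "boat", "bookstore", "breakfast",
  "cabin", "camera", "canyon", "carpet", "ceiling", "cellar", "chicken",
  "cinema", "coffee", "concert", "cookie", "cottage",
  "dentist", "desert", "dinner", "doctor", "dolphin", "driveway", "drum",
  "daisy", "diary", "dragon", "duck", "dessert",
  "factory", "farm", "fence", "festival", "fiddle", "fireplace", "flower",
  "forest", "fountain", "fridge", "frog", "furnace",
  "garage", "garden", "gallery", "gazebo", "guitar", "grocery", "gym",
  "goose", "gravel", "greenhouse", "griddle", "grove",
  "hallway", "hammock", "harbor", "hedge", "hill", "hospital", "hotel",
  "house", "hut", "hamper", "harp", "haystack",
  "kayak", "kennel", "kettle", "kitchen", "kite", "koala", "keyboard",
  "kiosk", "knapsack", "knoll", "kimono", "kazoo",
  "ladder", "lagoon", "lake", "lantern", "laundry", "lawn", "library",
  "lighthouse", "lobby", "locker", "loft", "lounge",
  "mailbox", "mango", "mansion", "market", "meadow", "mirror", "monument",
  "morning", "mountain", "museum", "music", "mural",
  "pantry", "parade", "park", "pasture", "patio", "piano", "picnic",
  "pillow", "pond", "porch", "puzzle", "puppet",
  "sandbox", "sauna", "school", "seminar", "shed", "shelf", "shore",
  "sidewalk", "sofa", "stadium", "stairs", "supper",
  "tavern", "teapot", "temple", "tent", "terrace", "theater", "toolbox",
  "tower", "trail", "tunnel", "turtle", "tulip",
  "wagon", "wallet", "wardrobe", "warehouse", "waterfall", "windmill", "wharf",
  "window", "woods", "workshop", "wreath", "walnut"
)

.abbrex_pronouns <- c("i", "you", "we", "they", "he", "she")
.abbrex_verbs <- c("like", "saw", "want", "made", "found", "took", "visited",
                   "watched", "bought", "fixed", "painted", "cleaned")
.abbrex_dets <- c("the", "a", "my", "your", "our", "that")
.abbrex_preps <- c("in", "at", "near", "behind", "by")

# Turn templates. Slot markers: P pronoun, V verb, D determiner, R preposition,
# N noun; anything else is a literal token (which may carry a trailing comma).
# `end` is the sentence-final punctuation appended without a space.
.abbrex_openers <- list(
  list(tokens = c("do", "you", "like", "the", "N"), end = "?"),
  list(tokens = c("how", "was", "the", "N", "today"), end = "?"),
  list(tokens = c("have", "you", "seen", "my", "N"), end = "?"),
  list(tokens = c("where", "is", "the", "N"), end = "?"),
  list(tokens = c("what", "happened", "at", "the", "N"), end = "?")
)

.abbrex_statements <- list(
  list(tokens = c("P", "V", "D", "N"), end = "."),
  list(tokens = c("P", "V", "D", "N", "R", "D", "N"), end = "."),
  list(tokens = c("ok,", "P", "V", "D", "N"), end = "."),
  list(tokens = c("yes,", "P", "V", "D", "N"), end = "."),
  list(tokens = c("well,", "the", "N", "was", "lovely"), end = "."),
  list(tokens = c("the", "N", "was", "great"), end = "."),
  list(tokens = c("P", "really", "V", "the", "N"), end = "."),
  list(tokens = c("maybe", "we", "can", "visit", "the", "N", "later"), end = "."),
  list(tokens = c("i", "think", "the", "N", "is", "near", "the", "N"), end = "."),
  list(tokens = c("did", "you", "V", "the", "N"), end = "?"),
  list(tokens = c("sounds", "good"), end = "."),
  list(tokens = c("ok,", "sounds", "good"), end = ".")
)

# Decoy lexicon for the oracle predictor: a handful of common words per
# initial letter, so that near-miss decoy phrases can swap in a different word
# sharing the initial (and, where needed, a typed prefix).
.abbrex_decoy_words <- c(
  "about", "after", "again", "apple", "always", "around",
  "because", "before", "better", "between", "being", "bright", "backyard",
  "basket", "bedtime",
  "could", "color", "coming", "certain", "change", "close",
  "doing", "down", "during", "different", "danger", "deep",
  "every", "early", "enough", "even", "extra", "easy",
  "first", "found", "friend", "funny", "forward", "fresh",
  "going", "good", "great", "green", "ground", "gentle",
  "happy", "having", "heavy", "hello", "hidden", "house",
  "inside", "into", "island", "ideal", "item", "early",
  "jolly", "just", "jumping", "junior", "joyful", "jacket",
  "keeping", "kind", "known", "kettle", "kitten", "key",
  "little", "long", "looking", "lovely", "lucky", "light",
  "maybe", "more", "making", "mostly", "middle", "modern",
  "never", "next", "night", "noisy", "normal", "narrow",
  "other", "over", "often", "only", "orange", "open",
  "pretty", "place", "playing", "plenty", "proud", "purple",
  "quite", "quick", "quiet", "quality", "question", "queen",
  "really", "right", "round", "ready", "rapid", "rustic",
  "something", "small", "sunny", "simple", "steady", "silver",
  "today", "together", "taking", "tiny", "total", "tender",
  "under", "until", "upper", "useful", "usual", "urban",
  "very", "visit", "value", "violet", "vivid", "vast",
  "window", "working", "warm", "wooden", "wide", "winter",
  "xenon", "xylem",
  "yellow", "young", "yonder", "yearly", "yummy", "yard",
  "zesty", "zigzag", "zonal", "zippy", "zero", "zone"
)
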
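# Bundled name lexicons for the synthetic population generator: small,
# frequency-ordered lists of common U.S.-style given and family names
# (most frequent first, so Zipf rank weighting applies directly).
# Users may supply their own lexicons via name_model().

FIRST_NAMES_FEMALE <- c(
  "mary", "patricia", "linda", "barbara", "elizabeth", "jennifer", "maria",
  "susan", "margaret", "dorothy", "lisa", "nancy", "karen", "betty", "helen",
  "sandra", "donna", "carol", "ruth", "sharon", "michelle", "laura", "sarah",
  "kimberly", "deborah", "jessica", "shirley", "cynthia", "angela", "melissa",
  "brenda", "amy", "anna", "rebecca", "virginia", "kathleen", "pamela",
  "martha", "debra", "amanda", "stephanie", "carolyn", "christine", "marie",
  "janet", "catherine", "frances", "ann", "joyce", "diane", "alice", "julie",
  "heather", "teresa", "doris", "gloria", "evelyn", "jean", "cheryl",
  "mildred", "katherine", "joan", "ashley", "judith", "rose", "janice",
  "kelly", "nicole", "judy", "christina", "kathy", "theresa", "beverly",
  "denise", "tammy", "irene", "jane", "lori", "rachel", "marilyn", "andrea",
  "kathryn", "louise", "sara", "anne", "jacqueline", "wanda", "bonnie",
  "julia", "ruby", "lois", "tina", "phyllis", "norma", "paula", "diana",
  "annie", "lillian", "emily", "robin", "peggy", "crystal", "gladys", "rita",
  "dawn", "connie", "florence", "tracy", "edna", "tiffany", "carmen", "rosa",
  "cindy", "grace", "wendy", "victoria", "edith", "kim", "sherry", "sylvia",
  "josephine", "thelma", "shannon", "sheila", "ethel", "ellen", "elaine",
  "marjorie", "carrie", "charlotte"
)

FIRST_NAMES_MALE <- c(
  "james", "john", "robert", "michael", "william", "david", "richard",
  "charles", "joseph", "thomas", "christopher", "daniel", "paul", "mark",
  "donald", "george", "kenneth", "steven", "edward", "brian", "ronald",
  "anthony", "kevin", "jason", "matthew", "gary", "timothy", "jose", "larry",
  "jeffrey", "frank", "scott", "eric", "stephen", "andrew", "raymond",
  "gregory", "joshua", "jerry", "dennis", "walter", "patrick", "peter",
  "harold", "douglas", "henry", "carl", "arthur", "ryan", "roger", "joe",
  "juan", "jack", "albert", "jonathan", "justin", "terry", "gerald", "keith",
  "samuel", "willie", "ralph", "lawrence", "nicholas", "roy", "benjamin",
  "bruce", "brandon", "adam", "harry", "fred", "wayne", "billy", "steve",
  "louis", "jeremy", "aaron", "randy", "howard", "eugene", "carlos",
  "russell", "bobby", "victor", "martin", "ernest", "phillip", "todd",
  "jesse", "craig", "alan", "shawn", "clarence", "sean", "philip", "chris",
  "johnny", "earl", "jimmy", "antonio", "danny", "bryan", "tony", "luis",
  "mike", "stanley", "leonard", "nathan", "dale", "manuel", "rodney",
  "curtis", "norman", "allen", "marvin", "vincent", "glenn", "jeffery",
  "travis", "jeff", "chad", "jacob", "lee", "melvin", "alfred", "kyle",
  "francis", "bradley", "jesus"
)

LAST_NAMES <- c(
  "smith", "johnson", "williams", "brown", "jones", "miller", "davis",
  "garcia", "rodriguez", "wilson", "martinez", "anderson", "taylor",
  "thomas", "hernandez", "moore", "martin", "jackson", "thompson", "white",
  "lopez", "lee", "gonzalez", "harris", "clark", "lewis", "robinson",
  "walker", "perez", "hall", "young", "allen", "sanchez", "wright", "king",
  "scott", "green", "baker", "adams", "nelson", "hill", "ramirez",
  "campbell", "mitchell", "roberts", "carter", "phillips", "evans", "turner",
  "torres", "parker", "collins", "edwards", "stewart", "flores", "morris",
  "nguyen", "murphy", "rivera", "cook", "rogers", "morgan", "peterson",
  "cooper", "reed", "bailey", "bell", "gomez", "kelly", "howard", "ward",
  "cox", "diaz", "richardson", "wood", "watson", "brooks", "bennett",
  "gray", "james", "reyes", "cruz", "hughes", "price", "myers", "long",
  "foster", "sanders", "ross", "morales", "powell", "sullivan", "russell",
  "ortiz", "jenkins", "gutierrez", "perry", "butler", "barnes", "fisher",
  "henderson", "coleman", "simmons", "patterson", "jordan", "reynolds",
  "hamilton", "graham", "kim", "gonzales", "alexander", "ramos", "wallace",
  "griffin", "west", "cole", "hayes", "chavez", "gibson", "bryant", "ellis",
  "stevens", "murray", "ford", "marshall", "owens", "mcdonald", "harrison",
  "ruiz", "kennedy", "wells", "alvarez", "woods", "mendoza", "castillo",
  "olson", "webb", "washington", "tucker", "freeman", "burns", "henry",
  "vasquez", "snyder", "simpson", "crawford", "jimenez", "porter", "mason",
  "shaw", "gordon", "wagner", "hunter", "romero", "hicks", "dixon", "hunt",
  "palmer", "robertson", "black", "holmes", "stone", "meyer", "boyd",
  "mills", "warren", "fox", "rose", "rice", "moreno", "schmidt", "patel",
  "ferguson", "nichols", "herrera", "medina", "ryan", "fernandez",
  "weaver", "daniels", "stephens", "gardner", "payne", "kelley", "dunn",
  "pierce", "arnold", "tran", "spencer", "peters", "hawkins", "grant",
  "hansen", "castro", "hoffman", "hart", "elliott", "cunningham", "knight",
  "bradley", "carroll", "hudson", "duncan", "armstrong", "berry", "andrews",
  "johnston", "ray", "lane", "riley", "carpenter", "perkins", "aguilar",
  "silva", "richards", "willis", "matthews", "chapman", "lawrence",
  "zimmerman", "soto", "lawson", "banks", "fields", "gomes", "wheeler",
  "chambers", "oliver", "fletcher", "watts", "bates", "yates", "hale",
  "rhodes", "pena", "beck", "newman", "haynes", "mccoy", "curtis", "walsh"
)

STREET_NAMES <- c(
  "oak", "maple", "cedar", "pine", "elm", "walnut", "chestnut", "willow",
  "birch", "spruce", "college", "university", "park", "main", "church",
  "mill", "spring", "ridge", "valley", "hill"
)
STREET_TYPES <- c("st", "ave", "rd", "ln", "dr", "ct")
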
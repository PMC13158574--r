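;;; adspeech bundled pronunciation lexicon, CMU Pronouncing Dictionary flat-file format.
;;; Hand-curated subset of common conversational / picture-description vocabulary,
;;; transcribed in General American ARPABET with stress digits.
A  AH0
A(2)  EY1
ABOUT  AH0 B AW1 T
AFTER  AE1 F T ER0
ALL  AO1 L
ALSO  AO1 L S OW0
AND  AH0 N D
AND(2)  AE1 N D
ANOTHER  AH0 N AH1 DH ER0
ANY  EH1 N IY0
ARE  AA1 R
AROUND  ER0 AW1 N D
AS  AE1 Z
ASK  AE1 S K
ASTRONAUT  AE1 S T R AH0 N AO2 T
AT  AE1 T
AWAY  AH0 W EY1
BACK  B AE1 K
BE  B IY1
BECAUSE  B IH0 K AO1 Z
BEEN  B IH1 N
BEFORE  B IH0 F AO1 R
BEHIND  B IH0 HH AY1 N D
BIG  B IH1 G
BLACK  B L AE1 K
BLUE  B L UW1
BOTH  B OW1 TH
BOTTLE  B AA1 T AH0 L
BOWL  B OW1 L
BOY  B OY1
BREAD  B R EH1 D
BREAK  B R EY1 K
BROTHER  B R AH1 DH ER0
BUT  B AH1 T
BY  B AY1
CABINET  K AE1 B AH0 N AH0 T
CAKE  K EY1 K
CAN  K AE1 N
CAT  K AE1 T
CHAIR  CH EH1 R
CHILD  CH AY1 L D
CHILDREN  CH IH1 L D R AH0 N
CLEAN  K L IY1 N
CLIMB  K L AY1 M
CLIMBING  K L AY1 M IH0 NG
CLOCK  K L AA1 K
CLOSE  K L OW1 S
COOKIE  K UH1 K IY0
COOKIES  K UH1 K IY0 Z
COULD  K UH1 D
COUNTER  K AW1 N T ER0
CUP  K AH1 P
CUPS  K AH1 P S
CURTAIN  K ER1 T AH0 N
CURTAINS  K ER1 T AH0 N Z
DAY  D EY1
DISH  D IH1 SH
DISHES  D IH1 SH IH0 Z
DO  D UW1
DOING  D UW1 IH0 NG
DOWN  D AW1 N
DRY  D R AY1
DRYING  D R AY1 IH0 NG
EAT  IY1 T
EIGHT  EY1 T
FALL  F AO1 L
FALLING  F AO1 L IH0 NG
FALLS  F AO1 L Z
FAUCET  F AO1 S AH0 T
FEET  F IY1 T
FIRST  F ER1 S T
FLOOR  F L AO1 R
FLOW  F L OW1
FOR  F AO1 R
FROM  F R AH1 M
FRONT  F R AH1 N T
FULL  F UH1 L
GARDEN  G AA1 R D AH0 N
GET  G EH1 T
GETTING  G EH1 T IH0 NG
GIRL  G ER1 L
GIVE  G IH1 V
GLASS  G L AE1 S
GO  G OW1
GOING  G OW1 IH0 NG
GOOD  G UH1 D
GRAB  G R AE1 B
GRASS  G R AE1 S
GREEN  G R IY1 N
HAND  HH AE1 N D
HANDS  HH AE1 N D Z
HAS  HH AE1 Z
HAVE  HH AE1 V
HE  HH IY1
HER  HH ER1
HERE  HH IY1 R
HIM  HH IH1 M
HIS  HH IH1 Z
HOME  HH OW1 M
HOUSE  HH AW1 S
HOW  HH AW1
I  AY1
IN  IH0 N
INTO  IH1 N T UW0
IS  IH1 Z
IT  IH1 T
JAR  JH AA1 R
JUST  JH AH1 S T
KITCHEN  K IH1 CH AH0 N
KNOW  N OW1
LADDER  L AE1 D ER0
LADY  L EY1 D IY0
LEFT  L EH1 F T
LIKE  L AY1 K
LITTLE  L IH1 T AH0 L
LOOK  L UH1 K
LOOKING  L UH1 K IH0 NG
MAKE  M EY1 K
MAN  M AE1 N
MAYBE  M EY1 B IY0
MILK  M IH1 L K
MOM  M AA1 M
MOTHER  M AH1 DH ER0
MOUTH  M AW1 TH
MUCH  M AH1 CH
MY  M AY1
NEAR  N IH1 R
NO  N OW1
NOT  N AA1 T
NOW  N AW1
OF  AH1 V
OFF  AO1 F
ON  AA1 N
ONE  W AH1 N
OPEN  OW1 P AH0 N
OTHER  AH1 DH ER0
OUT  AW1 T
OUTSIDE  AW1 T S AY1 D
OVER  OW1 V ER0
OVERFLOW  OW1 V ER0 F L OW2
OVERFLOWING  OW1 V ER0 F L OW2 IH0 NG
PLATE  P L EY1 T
PLAY  P L EY1
PLEASE  P L IY1 Z
POUR  P AO1 R
POURING  P AO1 R IH0 NG
PUT  P UH1 T
RAIN  R EY1 N
REACH  R IY1 CH
REACHING  R IY1 CH IH0 NG
RIGHT  R AY1 T
RUN  R AH1 N
RUNNING  R AH1 N IH0 NG
SAY  S EY1
SCHOOL  S K UW1 L
SCRAPE  S K R EY1 P
SCREAM  S K R IY1 M
SEE  S IY1
SEEMS  S IY1 M Z
SHE  SH IY1
SHELF  SH EH1 L F
SHOE  SH UW1
SINK  S IH1 NG K
SISTER  S IH1 S T ER0
SIT  S IH1 T
SMALL  S M AO1 L
SMILE  S M AY1 L
SNACK  S N AE1 K
SO  S OW1
SOME  S AH1 M
SOMETHING  S AH1 M TH IH0 NG
SPILL  S P IH1 L
SPILLING  S P IH1 L IH0 NG
SPLASH  S P L AE1 SH
SPRING  S P R IH1 NG
SQUARE  S K W EH1 R
STAND  S T AE1 N D
STANDING  S T AE1 N D IH0 NG
STEAL  S T IY1 L
STEALING  S T IY1 L IH0 NG
STOOL  S T UW1 L
STRAW  S T R AO1
STREAM  S T R IY1 M
STREET  S T R IY1 T
STRING  S T R IH1 NG
STRONG  S T R AO1 NG
SUMMER  S AH1 M ER0
TABLE  T EY1 B AH0 L
TAKE  T EY1 K
TAKING  T EY1 K IH0 NG
TALL  T AO1 L
THAT  DH AE1 T
THE  DH AH0
THE(2)  DH IY0
THEIR  DH EH1 R
THEM  DH EH1 M
THEN  DH EH1 N
THERE  DH EH1 R
THESE  DH IY1 Z
THEY  DH EY1
THING  TH IH1 NG
THINK  TH IH1 NG K
THIS  DH IH1 S
THREE  TH R IY1
THROUGH  TH R UW1
TIME  T AY1 M
TIP  T IH1 P
TIPPING  T IH1 P IH0 NG
TO  T UW1
TREE  T R IY1
TRYING  T R AY1 IH0 NG
TWO  T UW1
UH  AH1
UM  AH1 M
UP  AH1 P
VERY  V EH1 R IY0
WANT  W AA1 N T
WANTS  W AA1 N T S
WAS  W AA1 Z
WASH  W AA1 SH
WASHING  W AA1 SH IH0 NG
WATER  W AO1 T ER0
WE  W IY1
WELL  W EH1 L
WET  W EH1 T
WHAT  W AH1 T
WHEN  W EH1 N
WHERE  W EH1 R
WHICH  W IH1 CH
WHILE  W AY1 L
WHITE  W AY1 T
WHO  HH UW1
WILL  W IH1 L
WINDOW  W IH1 N D OW0
WITH  W IH1 DH
WOMAN  W UH1 M AH0 N
WOULD  W UH1 D
YARD  Y AA1 R D
YES  Y EH1 S
YOU  Y UW1
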
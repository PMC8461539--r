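raw,normalized
Can't stop HPV-vaccine lies & myths,cannot stop hpv vaccine lies and myths
@a @b @c gardasil,MENTION MENTION gardasil
RT @user: Gardasil9 caused 2x the pain! https://t.co/abc #vaccineinjury,RT MENTION gardasil NUMBER caused NUMBER x the pain vaccineinjury
,
"You'll regret it... 3,000 girls harmed",you will regret it NUMBER girls harmed
HPV vaccine prevents cervical cancer http://bit.ly/xyz,hpv vaccine prevents cervical cancer
the shot is SAFE and effective!!!,the shot is safe and effective
@mom_of_3 won't vaccinate her kids,MENTION will not vaccinate her kids
90% protection against HPV-related cancers,NUMBER protection against hpv related cancers
It's a hoax; don't believe them,it is a hoax do not believe them
RT @cdc: updated guidance w/ new schedule,RT MENTION updated guidance w new schedule
Vaccines & autism: there is NO link,vaccines and autism there is no link
my daughter fainted 2hrs after the 2nd dose,my daughter fainted NUMBER hrs after the NUMBER nd dose
#Gardasil #truth @user1 @user2 @user3 @user4,gardasil truth MENTION MENTION
doctors recommend the vaccine for boys/girls aged 11-12,doctors recommend the vaccine for boys girls aged NUMBER NUMBER
"She's fine now, thanks!",she is fine now thanks
that's what they said in 2015...,that is what they said in NUMBER
BREAKING: vaccine recalled in Japan?!,breaking vaccine recalled in japan
who's responsible for these adverse events?,who is responsible for these adverse events
"I'm not anti-vax, I'm pro-safety",i am not anti vax i am pro safety
u.s. uptake remains low (56.8%),u s uptake remains low NUMBER
What's in the HPV shot?,what is in the hpv shot
RT RT RT spam spam,RT RT RT spam spam
premature ovarian failure linked to gardasil,premature ovarian failure linked to gardasil
  leading   spaces and	tabs  ,leading spaces and tabs
ALL CAPS MESSAGE ABOUT VACCINES,all caps message about vaccines
mixed CASE with MENTION token inside,mixed case with MENTION token inside
"due to the vaccine, she developed chronic pain",due to the vaccine she developed chronic pain
5 reasons to vaccinate your child today,NUMBER reasons to vaccinate your child today
no url here www.example.com but this was one,no url here but this was one
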